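#' Knudtson pairwise branch combination
#'
#' Revised Knudtson combination of two branch calibers into an equivalent
#' trunk caliber: `W = c * sqrt(W1^2 + W2^2)` with `c = 0.88` for arteries
#' and `c = 0.95` for veins.  Symmetric in its two arguments.
#'
#' @param w1,w2 Branch widths (um), nonnegative.
#' @param vessel_class `"artery"` or `"vein"`.
#' @return Combined caliber (um).
#' @export
knudtson_combine <- function(w1, w2, vessel_class = c("artery", "vein")) {
  vessel_class <- match.arg(vessel_class)
  if (any(c(w1, w2) < 0)) stop("widths must be nonnegative", call. = FALSE)
  c0 <- if (vessel_class == "artery") 0.88 else 0.95
  c0 * sqrt(w1^2 + w2^2)
}

#' Central retinal vessel equivalent from trunk calibers
#'
#' Standard Knudtson reduction: the `n_largest` widest trunks are reduced
#' pairwise, each round combining the current largest with the current
#' smallest and carrying the median element of odd-sized rounds, until a
#' single equivalent remains.
#'
#' @param widths Trunk calibers (um), at least one.
#' @param vessel_class `"artery"` or `"vein"`.
#' @param n_largest Number of widest trunks entering the reduction.
#' @return Equivalent caliber (um); `NA` for an empty width list.
#' @export
central_equivalent <- function(widths, vessel_class = c("artery", "vein"),
                               n_largest = 6L) {
  vessel_class <- match.arg(vessel_class)
  widths <- widths[!is.na(widths)]
  if (length(widths) == 0L) return(NA_real_)
  if (any(widths < 0)) stop("widths must be nonnegative", call. = FALSE)
  cur <- sort(widths, decreasing = TRUE)
  cur <- cur[seq_len(min(n_largest, length(cur)))]
  while (length(cur) > 1L) {
    cur <- sort(cur)
    n <- length(cur)
    half <- n %/% 2L
    nxt <- numeric(0)
    for (i in seq_len(half))
      nxt <- c(nxt, knudtson_combine(cur[i], cur[n + 1L - i], vessel_class))
    if (n %% 2L == 1L) nxt <- c(nxt, cur[half + 1L])  # carry the median
    cur <- nxt
  }
  cur
}

#' CRAE, CRVE and AVR from Zone B trunk widths
#'
#' Per class, trunk caliber is the median per-point width of each Zone B
#' segment; the class equivalent combines the six largest trunks via
#' [central_equivalent()].  AVR = CRAE / CRVE.
#'
#' @param artery_graph,vein_graph `vessel_graph`s with width annotations.
#' @param annuli A [zone_annuli()].
#' @param n_largest Trunks entering the reduction.
#' @return Object of class `caliber_panel`: `crae`, `crve`, `avr` and the
#'   contributing per-class trunk width lists (um).  A class with no Zone B
#'   segment yields `NA` for its equivalent (and for AVR).
#' @export
caliber_panel <- function(artery_graph, vein_graph, annuli, n_largest = 6L) {
  trunk_widths <- function(graph) {
    if (is.null(graph)) return(numeric(0))
    zb <- clip_to_zone(graph, annuli, "B")
    vapply(zb$segments, function(s) median(s$widths), numeric(1))
  }
  wa <- trunk_widths(artery_graph)
  wv <- trunk_widths(vein_graph)
  crae <- if (length(wa)) central_equivalent(wa, "artery", n_largest)
          else NA_real_
  crve <- if (length(wv)) central_equivalent(wv, "vein", n_largest)
          else NA_real_
  structure(list(crae = crae, crve = crve, avr = crae / crve,
                 contributing_widths = list(artery = wa, vein = wv)),
            class = "caliber_panel")
}

#' @export
print.caliber_panel <- function(x, ...) {
  cat(sprintf("caliber_panel: CRAE %.1f um  CRVE %.1f um  AVR %.3f\n",
              x$crae, x$crve, x$avr))
  cat(sprintf("  trunks used: %d arterial, %d venular\n",
              length(x$contributing_widths$artery),
              length(x$contributing_widths$vein)))
  invisible(x)
}
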