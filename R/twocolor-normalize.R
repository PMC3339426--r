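#' Log-ratio / average-intensity transform
#'
#' Converts corrected two-channel intensities to M/A space with the channel
#' roles resolved from the array's dye orientation, so that M is always
#' log2(treatment / reference) regardless of which dye carried the treatment
#' sample. Dye-swapped arrays therefore need no sign handling downstream.
#'
#' @param corrected a \code{\link{normexp_background}} result.
#' @return An \code{MAData} data frame: \code{array_id}, \code{spot_id},
#'   \code{probe_id}, \code{print_tip_group} (the block index), \code{M},
#'   \code{A}, \code{weight}.
#' @export
compute_MA <- function(corrected) {
  stopifnot(inherits(corrected, "NormexpCorrected"))
  arr <- corrected$array
  s <- arr$spots
  if (arr$dye_orientation == "treatment_in_ch1") {
    trt <- corrected$ch1; ref <- corrected$ch2
  } else {
    trt <- corrected$ch2; ref <- corrected$ch1
  }
  w <- if ("weight" %in% names(s)) s$weight else rep(1, nrow(s))
  out <- data.frame(array_id = arr$array_id, spot_id = s$spot_id,
                    probe_id = s$probe_id, print_tip_group = s$block,
                    M = log2(trt / ref), A = 0.5 * log2(trt * ref),
                    weight = w, stringsAsFactors = FALSE)
  class(out) <- c("MAData", "data.frame")
  out
}

#' Print-tip loess normalization
#'
#' Removes intensity-dependent dye bias within each print-tip group (block)
#' by local regression of M on A: the loess fit is subtracted from M,
#' evaluated at each spot's A. Weight-0 (flagged) spots are excluded from
#' fitting but still normalized. Groups with fewer than \code{min_spots}
#' usable spots fall back to a single global loess with a warning. A is
#' unchanged.
#'
#' @param ma an \code{\link{compute_MA}} result.
#' @param span loess span (default 0.3).
#' @param iterations robustifying iterations (default 4, tricube weights,
#'   degree 1).
#' @param min_spots minimum usable spots per group before falling back.
#' @return The normalized \code{MAData}.
#' @export
printtip_loess <- function(ma, span = 0.3, iterations = 4L, min_spots = 10L) {
  stopifnot(inherits(ma, "MAData"), span > 0, span <= 1)
  fit_group <- function(idx) {
    use <- idx[ma$weight[idx] > 0 & is.finite(ma$M[idx]) & is.finite(ma$A[idx])]
    if (length(use) < 2L) return(rep(0, length(idx)))
    fit <- stats::loess(M ~ A, data = ma[use, ], span = span, degree = 1,
                        family = "symmetric",
                        control = stats::loess.control(iterations = iterations,
                                                       surface = "direct"))
    stats::predict(fit, newdata = data.frame(A = ma$A[idx]))
  }
  groups <- split(seq_len(nrow(ma)), ma$print_tip_group)
  usable <- vapply(groups, function(idx) sum(ma$weight[idx] > 0), numeric(1))
  small <- usable < min_spots
  if (any(small)) {
    warning("print-tip group(s) ", paste(names(groups)[small], collapse = ", "),
            " have < ", min_spots, " usable spots; using global loess for them")
    global_fit <- fit_group(seq_len(nrow(ma)))
  }
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    trend <- if (small[g]) global_fit[idx] else fit_group(idx)
    ma$M[idx] <- ma$M[idx] - trend
  }
  ma
}

#' Stack per-array MA data into spot-by-array matrices
#'
#' Aligns arrays by spot id (all arrays must share the print layout) and
#' returns matrices suitable for the linear-model stage.
#'
#' @param mas list of \code{MAData}, one per array.
#' @return list of class \code{MAStack}: \code{M}, \code{A}, \code{weights}
#'   (spots x arrays), \code{probe_id}, \code{spot_id},
#'   \code{print_tip_group}, \code{array_ids}.
#' @export
stack_ma <- function(mas) {
  stopifnot(length(mas) >= 1L, all(vapply(mas, inherits, logical(1), "MAData")))
  ref <- mas[[1]]
  key <- ref$spot_id
  grab <- function(col) vapply(mas, function(m) {
    i <- match(key, m$spot_id)
    if (anyNA(i)) stop("arrays do not share the spot layout")
    m[[col]][i]
  }, numeric(length(key)))
  M <- grab("M"); A <- grab("A"); W <- grab("weight")
  ids <- vapply(mas, function(m) m$array_id[1], character(1))
  dimnames(M) <- dimnames(A) <- dimnames(W) <- list(key, ids)
  structure(list(M = M, A = A, weights = W, probe_id = ref$probe_id,
                 spot_id = key, print_tip_group = ref$print_tip_group,
                 array_ids = ids),
            class = "MAStack")
}
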