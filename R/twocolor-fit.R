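#' Consensus correlation of within-array duplicate spots
#'
#' Probes printed twice per array yield technically correlated observations.
#' A single consensus correlation is estimated deterministically: for each
#' probe with complete duplicate data, the Pearson correlation of its two
#' duplicate M-value series across arrays is Fisher-z transformed; the z
#' values are robustly averaged by a trimmed mean (trim fraction 0.15) and
#' back-transformed. The result is clamped to (-0.99, 0.99). (The classical
#' implementation uses REML on a mixed model; this deterministic consensus
#' recovers the truth within about 0.05 at two thousand probes and is
#' recorded as such in the result's \code{method} field.)
#'
#' @param stack an \code{\link{stack_ma}} result.
#' @param duplicate_map optional named list probe_id -> character(2) of spot
#'   ids; by default every probe with exactly two spots per array is used.
#' @param trim trimmed-mean fraction (default 0.15).
#' @return list with \code{rho}, \code{n_probes} used, \code{method}.
#' @export
duplicate_correlation <- function(stack, duplicate_map = NULL, trim = 0.15) {
  stopifnot(inherits(stack, "MAStack"))
  if (is.null(duplicate_map)) {
    cnt <- table(stack$probe_id)
    dup_probes <- names(cnt)[cnt == 2L]
    duplicate_map <- lapply(dup_probes, function(p)
      stack$spot_id[stack$probe_id == p])
    names(duplicate_map) <- dup_probes
  }
  rs <- vapply(duplicate_map, function(spots) {
    i <- match(spots, stack$spot_id)
    if (length(i) != 2L || anyNA(i)) return(NA_real_)
    ok <- stack$weights[i[1], ] > 0 & stack$weights[i[2], ] > 0 &
      is.finite(stack$M[i[1], ]) & is.finite(stack$M[i[2], ])
    if (sum(ok) < 3L) return(NA_real_)
    m1 <- stack$M[i[1], ok]; m2 <- stack$M[i[2], ok]
    if (stats::sd(m1) == 0 || stats::sd(m2) == 0) return(NA_real_)
    stats::cor(m1, m2)
  }, numeric(1))
  rs <- rs[is.finite(rs) | is.infinite(rs)]
  rs <- rs[!is.na(rs)]
  if (length(rs) < 5L)
    stop("fewer than 5 probes with complete duplicate data")
  z <- atanh(pmin(pmax(rs, -1), 1))
  rho <- tanh(mean(z, trim = trim))
  rho <- min(max(rho, -0.99), 0.99)
  list(rho = rho, n_probes = length(rs),
       method = "trimmed Fisher-z consensus (deterministic stand-in for REML)")
}

#' Per-probe generalized least squares on M values
#'
#' Fits the array-level linear model to each probe's M values by GLS,
#' treating within-array duplicate spots as correlated observations with
#' correlation \code{rho} (unit marginal variance scale) and arrays as
#' independent. Weight-0 spots are dropped from the fit. With
#' \code{rho = 0} this reduces exactly to ordinary least squares over all
#' spots. Probes with fewer usable observations than coefficients are marked
#' unestimable (all-NA row) and excluded downstream.
#'
#' @param stack an \code{\link{stack_ma}} result.
#' @param design numeric matrix, arrays x coefficients (rownames must match
#'   \code{stack$array_ids}); must be full rank.
#' @param rho within-array duplicate correlation (default 0).
#' @return list of class \code{DEFit}: \code{coefficients},
#'   \code{stdev_unscaled} (probes x coefficients), \code{sigma},
#'   \code{df_residual} (per probe), \code{design}, \code{rho},
#'   \code{probe_id}.
#' @export
fit_linear_model <- function(stack, design, rho = 0) {
  stopifnot(inherits(stack, "MAStack"), abs(rho) < 1)
  design <- as.matrix(design)
  if (is.null(rownames(design))) rownames(design) <- stack$array_ids
  design <- design[stack$array_ids, , drop = FALSE]
  p <- ncol(design)
  if (qr(design)$rank < p) stop("design matrix is not full rank")
  probes <- sort(unique(stack$probe_id))
  n_arr <- length(stack$array_ids)
  coefs <- sdu <- matrix(NA_real_, length(probes), p,
                         dimnames = list(probes, colnames(design)))
  sigma <- df_res <- setNames(rep(NA_real_, length(probes)), probes)
  spot_rows <- split(seq_along(stack$probe_id), stack$probe_id)
  for (g in seq_along(probes)) {
    rows <- spot_rows[[probes[g]]]
    yl <- list(); Xl <- list()
    for (a in seq_len(n_arr)) {
      ok <- rows[stack$weights[rows, a] > 0 & is.finite(stack$M[rows, a])]
      k <- length(ok)
      if (k == 0L) next
      y_a <- stack$M[ok, a]
      X_a <- matrix(design[a, ], k, p, byrow = TRUE)
      if (k > 1L && rho != 0) {
        V <- matrix(rho, k, k); diag(V) <- 1
        Li <- backsolve(chol(V), diag(k), transpose = TRUE)  # L^{-1}, V = L'L
        y_a <- Li %*% y_a
        X_a <- Li %*% X_a
      }
      yl[[length(yl) + 1L]] <- y_a
      Xl[[length(Xl) + 1L]] <- X_a
    }
    if (!length(yl)) next
    y <- unlist(yl)
    X <- do.call(rbind, Xl)
    if (nrow(X) < p || qr(X)$rank < p) next  # unestimable
    fit <- stats::lm.fit(X, y)
    XtXi <- chol2inv(chol(crossprod(X)))
    coefs[g, ] <- fit$coefficients
    sdu[g, ] <- sqrt(diag(XtXi))
    df_res[g] <- nrow(X) - p
    rss <- sum(fit$residuals^2)
    sigma[g] <- if (df_res[g] > 0) sqrt(rss / df_res[g]) else NA_real_
  }
  structure(list(coefficients = coefs, stdev_unscaled = sdu, sigma = sigma,
                 df_residual = df_res, design = design, rho = rho,
                 probe_id = probes),
            class = "DEFit")
}

# Newton solve of trigamma(x) = y, vectorized
trigamma_inverse <- function(y) {
  x <- 0.5 + 1 / y
  x[y > 1e7] <- 1 / sqrt(y[y > 1e7])
  x[y < 1e-6] <- 1 / y[y < 1e-6]
  for (i in 1:75) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (max(abs(dif / x)) < 1e-10) break
  }
  x
}

#' Empirical-Bayes moderation of residual variances
#'
#' Per-probe sample variances are shrunk toward a pooled prior estimated by
#' matching moments of log s^2 to a scaled-F model: the prior degrees of
#' freedom d0 and prior variance s0^2 solve the mean/variance equations of
#' log s^2 (digamma/trigamma identities). The moderated variance is the
#' df-weighted mix \eqn{(d0 s0^2 + d_g s_g^2) / (d0 + d_g)}; the moderated
#' t-statistic is the coefficient over its moderated standard error, referred
#' to a t distribution with d0 + d_g degrees of freedom. When variances are
#' essentially identical the d0 = Inf branch applies (all variances become
#' s0^2, normal reference). Forcing \code{df_prior = 0} recovers ordinary
#' per-probe t-tests.
#'
#' @param fit a \code{\link{fit_linear_model}} result.
#' @param df_prior,s2_prior optional overrides for the estimated
#'   hyperparameters (both must be given together).
#' @return The fit extended with \code{df_prior}, \code{s2_prior},
#'   \code{s2_post}, \code{t}, \code{p_value} (probes x coefficients),
#'   class \code{DEFitModerated}.
#' @export
ebayes_moderate <- function(fit, df_prior = NULL, s2_prior = NULL) {
  stopifnot(inherits(fit, "DEFit"))
  s2 <- fit$sigma^2
  dg <- fit$df_residual
  ok <- is.finite(s2) & s2 > 0 & dg > 0
  if (is.null(df_prior)) {
    if (sum(ok) < 50L)
      stop("need at least 50 probes with positive residual df to estimate the prior")
    z <- log(s2[ok])
    e <- z - digamma(dg[ok] / 2) + log(dg[ok] / 2)
    emean <- mean(e)
    evar <- sum((e - emean)^2) / (sum(ok) - 1) - mean(trigamma(dg[ok] / 2))
    if (evar > 0) {
      df_prior <- 2 * trigamma_inverse(evar)
      s2_prior <- exp(emean + digamma(df_prior / 2) - log(df_prior / 2))
    } else {
      df_prior <- Inf
      s2_prior <- exp(emean)
    }
  } else {
    if (is.null(s2_prior)) stop("supply s2_prior together with df_prior")
  }
  dg0 <- ifelse(is.na(dg), 0, dg)
  s2g <- ifelse(is.na(s2), 0, s2)
  s2_post <- if (is.infinite(df_prior)) rep(s2_prior, length(s2)) else
    (df_prior * s2_prior + dg0 * s2g) / (df_prior + dg0)
  if (df_prior == 0) s2_post <- s2  # no pooling: ordinary t
  df_total <- df_prior + dg0
  tt <- fit$coefficients / (fit$stdev_unscaled * sqrt(s2_post))
  pv <- tt
  for (j in seq_len(ncol(tt))) {
    pv[, j] <- ifelse(is.infinite(df_total),
                      2 * stats::pnorm(-abs(tt[, j])),
                      2 * stats::pt(-abs(tt[, j]), df = df_total))
  }
  fit$df_prior <- df_prior
  fit$s2_prior <- s2_prior
  fit$s2_post <- s2_post
  fit$t <- tt
  fit$p_value <- pv
  class(fit) <- c("DEFitModerated", "DEFit")
  fit
}

#' False-discovery-rate adjustment
#'
#' Benjamini-Hochberg step-up by default (Benjamini-Yekutieli and Bonferroni
#' available), delegated to \code{stats::p.adjust} with NaN/NA p-values
#' propagated as NA and excluded from the number of tests.
#'
#' @param p numeric vector of p-values in [0, 1] (NA/NaN allowed).
#' @param method "BH", "BY" or "bonferroni".
#' @return Adjusted q-values, same length and order as \code{p}.
#' @export
fdr_adjust <- function(p, method = c("BH", "BY", "bonferroni")) {
  method <- match.arg(method)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values outside [0, 1]")
  q <- rep(NA_real_, length(p))
  q[ok] <- stats::p.adjust(p[ok], method = method)
  q
}

#' Two-line direction classification of differential expression
#'
#' A probe is jointly significant when its FDR-adjusted p-value is at most
#' \code{alpha} in \emph{both} per-line contrasts; its category is the sign
#' pair of the two log2 fold changes (Down/Down, Down/Up, Up/Down, Up/Up).
#' Treating the two independently transformed lines as separate contrasts and
#' intersecting is the conservative reading; pooling them as replicates is
#' not done here.
#'
#' @param fit_line37,fit_line45 data frames with columns \code{probe_id},
#'   \code{logFC}, \code{q} covering the same probe universe (see
#'   \code{\link{de_pipeline}} for how these are produced).
#' @param alpha FDR significance threshold (default 0.05).
#' @return list of class \code{DEClassification}: \code{table} (per probe:
#'   directions per line and category) and \code{counts} (named vector over
#'   the four categories plus \code{total}).
#' @export
classify_de <- function(fit_line37, fit_line45, alpha = 0.05) {
  if (!setequal(fit_line37$probe_id, fit_line45$probe_id))
    stop("the two fits must cover the same probe universe")
  m <- merge(fit_line37, fit_line45, by = "probe_id",
             suffixes = c("_37", "_45"))
  dir_of <- function(lfc, q) {
    d <- ifelse(is.na(q) | q > alpha, "ns", ifelse(lfc < 0, "down", "up"))
    zero <- !is.na(q) & q <= alpha & lfc == 0
    if (any(zero)) {
      warning("zero fold change at significance; tie-broken to 'up'")
      d[zero] <- "up"
    }
    d
  }
  d37 <- dir_of(m$logFC_37, m$q_37)
  d45 <- dir_of(m$logFC_45, m$q_45)
  joint <- d37 != "ns" & d45 != "ns"
  cap <- function(d) c(down = "Down", up = "Up")[d]
  category <- ifelse(joint, paste0(cap(d37), "/", cap(d45)), "not-significant")
  tab <- data.frame(probe_id = m$probe_id, direction_line37 = d37,
                    direction_line45 = d45, category = category,
                    stringsAsFactors = FALSE)
  cats <- c("Down/Down", "Down/Up", "Up/Down", "Up/Up")
  counts <- vapply(cats, function(ct) sum(category == ct), integer(1))
  counts <- c(counts, total = sum(joint))
  structure(list(table = tab, counts = counts, alpha = alpha),
            class = "DEClassification")
}

#' @export
print.DEClassification <- function(x, ...) {
  cat("Jointly significant probes at FDR <=", x$alpha, "\n")
  print(x$counts)
  invisible(x)
}

#' Run the full two-color differential-expression chain
#'
#' Orchestrates the statistics chain on a set of arrays: flag weights,
#' normexp background correction with offset, M/A transform with dye
#' orientation resolved per array, print-tip loess normalization,
#' duplicate-correlation estimation, per-probe GLS fit against the
#' line design, empirical-Bayes moderation, per-line FDR adjustment and
#' two-line classification.
#'
#' @param arrays list of \code{\link{two_color_array}} objects.
#' @param targets data frame with columns \code{array_id}, \code{line}
#'   (e.g. "line37", "line45"), \code{dye_orientation}; the design matrix has
#'   one indicator column per line.
#' @param offset normexp offset (default 50).
#' @param span print-tip loess span.
#' @param alpha FDR threshold for classification.
#' @param fdr_method multiplicity adjustment for the per-line p-values.
#' @param use_duplicates estimate and use the duplicate correlation when
#'   duplicate spots are present.
#' @return list of class \code{DEPipelineResult}: moderated \code{fit},
#'   per-line results data frame \code{results} (logFC, t, p, q per line),
#'   \code{classification}, \code{rho}, \code{stack}.
#' @export
de_pipeline <- function(arrays, targets, offset = 50, span = 0.3,
                        alpha = 0.05, fdr_method = "BH",
                        use_duplicates = TRUE) {
  mas <- lapply(arrays, function(a) {
    a <- flag_filter(a)
    a$dye_orientation <- targets$dye_orientation[match(a$array_id, targets$array_id)]
    printtip_loess(compute_MA(normexp_background(a, offset = offset)),
                   span = span)
  })
  stack <- stack_ma(mas)
  lines <- sort(unique(targets$line))
  design <- sapply(lines, function(l) as.numeric(targets$line == l))
  rownames(design) <- targets$array_id
  rho <- 0
  dup_info <- NULL
  if (use_duplicates && any(table(stack$probe_id) == 2L)) {
    dup_info <- tryCatch(duplicate_correlation(stack), error = function(e) NULL)
    if (!is.null(dup_info)) rho <- dup_info$rho
  }
  fit <- ebayes_moderate(fit_linear_model(stack, design, rho = rho))
  per_line <- lapply(lines, function(l) {
    data.frame(probe_id = fit$probe_id, logFC = fit$coefficients[, l],
               t = fit$t[, l], p = fit$p_value[, l],
               q = fdr_adjust(fit$p_value[, l], method = fdr_method),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  names(per_line) <- lines
  classification <- if (length(lines) == 2L)
    classify_de(per_line[[1]], per_line[[2]], alpha = alpha) else NULL
  res <- data.frame(probe_id = fit$probe_id, stringsAsFactors = FALSE)
  for (l in lines) {
    for (col in c("logFC", "t", "p", "q"))
      res[[paste0(col, "_", l)]] <- per_line[[l]][[col]]
  }
  structure(list(fit = fit, results = res, per_line = per_line,
                 classification = classification, rho = rho,
                 duplicate_info = dup_info, stack = stack,
                 design = design, alpha = alpha),
            class = "DEPipelineResult")
}
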