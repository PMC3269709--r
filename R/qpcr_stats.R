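#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Ct on log10 template concentration over a
#' dilution series; amplification efficiency is derived from the slope via
#' [efficiency()].
#'
#' @param points Data frame with columns `log10_conc` and `ct` (at least 3
#'   points, non-degenerate concentrations).
#' @return Object of class `standard_curve`: `slope`, `intercept`,
#'   `r_squared`, `efficiency`, `points`.
#' @examples
#' pts <- data.frame(log10_conc = 0:-3, ct = -3.3125 * (0:-3) + 39.562)
#' fit_standard_curve(pts)
#' @export
fit_standard_curve <- function(points) {
  stopifnot(is.data.frame(points),
            all(c("log10_conc", "ct") %in% names(points)))
  points <- points[stats::complete.cases(points[c("log10_conc", "ct")]), ]
  if (nrow(points) < 3L)
    stop("a standard curve needs at least 3 points", call. = FALSE)
  if (length(unique(points$log10_conc)) < 2L)
    stop("all template concentrations are identical", call. = FALSE)
  fit <- lm(ct ~ log10_conc, data = points)
  slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  sst <- sum((points$ct - mean(points$ct))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else NA_real_
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 efficiency = if (slope < 0) efficiency(slope) else NA_real_,
                 points = points),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "<standard_curve> Ct = %.4f * log10(conc) + %.4f  (R^2 = %.4f, E = %s)\n",
    x$slope, x$intercept, round(x$r_squared, 4),
    if (is.na(x$efficiency)) "NA" else sprintf("%.4f", x$efficiency)))
  invisible(x)
}

#' qPCR amplification efficiency from a dilution-series slope
#'
#' `E = 10^(-1/slope)`; the ideal efficiency (perfect doubling each cycle)
#' is 2, reached at slope −log2(10) ≈ −3.3219.
#'
#' @param slope Standard-curve slope (must be negative).
#' @return Per-cycle amplification factor E.
#' @examples
#' efficiency(-3.3125)  # 2.0039
#' @export
efficiency <- function(slope) {
  stopifnot(is.numeric(slope), length(slope) == 1L)
  if (!is.finite(slope) || slope >= 0)
    stop("slope must be negative", call. = FALSE)
  10^(-1 / slope)
}

#' Read a Ct table / dilution series from TSV
#'
#' `read_ct_table()` expects columns `stage`, `replicate`, `ct_target`,
#' `ct_reference`; `read_dilution_series()` expects `log10_conc`, `ct`.
#'
#' @param path TSV file with a header line.
#' @return A data frame.
#' @export
read_ct_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("stage", "replicate", "ct_target", "ct_reference")
  if (!all(need %in% names(df)))
    stop(sprintf("Ct table must have columns: %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  df
}

#' @rdname read_ct_table
#' @export
read_dilution_series <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("log10_conc", "ct") %in% names(df)))
    stop("dilution series must have columns log10_conc, ct", call. = FALSE)
  df
}

#' Relative quantification by the 2^-ddCt method
#'
#' Per replicate, dCt = Ct(target) − Ct(reference gene); per stage, the
#' mean dCt; ddCt = mean dCt(stage) − mean dCt(calibrator stage); and
#' RQ = 2^−ddCt, so the calibrator's RQ is exactly 1. The per-stage
#' standard error is that of the replicate-level 2^−ddCt values. Duncan
#' letters (see [duncan_grouping()]) are computed on replicate-level dCt
#' (log scale, where variances are more homogeneous) when every stage has
#' at least 2 replicates; set `duncan_on = "rq"` to group on the linear
#' scale instead.
#'
#' @param data Data frame with columns `stage`, `replicate`, `ct_target`,
#'   `ct_reference` (see [read_ct_table()]).
#' @param calibrator Calibrator stage label (e.g. `"egg"`).
#' @param base Amplification factor used in `base^-ddCt` (default 2, the
#'   uncorrected method; pass a measured [efficiency()] for an
#'   efficiency-corrected RQ).
#' @param alpha Significance level for the Duncan letters.
#' @param duncan_on `"dct"` (default) or `"rq"`.
#' @return Data frame of class `rq_result`, one row per stage (input
#'   order): `stage`, `n`, `mean_dct`, `ddct`, `rq`, `se`, `letters`.
#' @export
delta_delta_ct <- function(data, calibrator, base = 2, alpha = 0.05,
                           duncan_on = c("dct", "rq")) {
  duncan_on <- match.arg(duncan_on)
  stopifnot(is.data.frame(data),
            all(c("stage", "replicate", "ct_target", "ct_reference")
                %in% names(data)))
  if (any(!is.finite(data$ct_target)) || any(!is.finite(data$ct_reference)))
    stop("non-finite Ct values", call. = FALSE)
  stages <- unique(as.character(data$stage))
  if (!calibrator %in% stages)
    stop(sprintf("calibrator stage '%s' not present", calibrator),
         call. = FALSE)
  data$dct <- data$ct_target - data$ct_reference
  dct_by_stage <- split(data$dct, factor(data$stage, levels = stages))
  mean_dct <- vapply(dct_by_stage, mean, numeric(1))
  cal_mean <- mean_dct[[calibrator]]
  ddct <- mean_dct - cal_mean
  rq <- base^(-ddct)
  # replicate-level RQs against the calibrator stage mean
  rq_reps <- lapply(dct_by_stage, function(v) base^(-(v - cal_mean)))
  se <- vapply(rq_reps, function(v)
    if (length(v) > 1L) sd(v) / sqrt(length(v)) else NA_real_, numeric(1))
  n <- vapply(dct_by_stage, length, integer(1))

  letters <- rep(NA_character_, length(stages))
  if (length(stages) >= 2L && all(n >= 2L)) {
    groups <- if (duncan_on == "dct") dct_by_stage else rq_reps
    letters <- duncan_grouping(groups, alpha = alpha)[stages]
  }
  out <- data.frame(stage = stages, n = unname(n),
                    mean_dct = unname(mean_dct), ddct = unname(ddct),
                    rq = unname(rq), se = unname(se),
                    letters = unname(letters), stringsAsFactors = FALSE)
  structure(out, class = c("rq_result", "data.frame"),
            calibrator = calibrator, base = base)
}

#' Duncan's multiple range test with letter display
#'
#' One-way ANOVA pooled error, then Duncan's least significant ranges
#' `R_p = q((1-alpha)^(p-1), p, df) * sqrt(MSE / n_h)` (studentized-range
#' quantiles at Duncan's protection levels, harmonic-mean group size) over
#' the rank-ordered means; a spanned range is not declared significant if
#' it lies inside a range already found non-significant. Means that are not
#' significantly different share a letter; letters are assigned in
#' descending-mean order. If every group has zero within-group variance but
#' means differ, each distinct mean gets its own letter.
#'
#' @param groups Named list of numeric replicate vectors (>= 2 groups, each
#'   with >= 2 replicates unless all variances are zero).
#' @param alpha Significance level in (0, 1).
#' @return Named character vector: group -> letter string, in input order.
#' @examples
#' duncan_grouping(list(a = c(1, 1.1, 0.9), b = c(5, 5.2, 4.9)))
#' @export
duncan_grouping <- function(groups, alpha = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 2L,
            alpha > 0, alpha < 1)
  if (is.null(names(groups)) || anyNA(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  k <- length(groups)
  ni <- vapply(groups, length, integer(1))
  means <- vapply(groups, mean, numeric(1))
  N <- sum(ni)
  df_err <- N - k
  sse <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1)))

  ord <- order(means, decreasing = TRUE)
  m_sorted <- means[ord]

  if (df_err < 1L || sse <= .Machine$double.eps * N) {
    # degenerate: no error estimate; distinct means are distinct letters
    uniq <- unique(round(m_sorted, 12))
    lab <- letters[match(round(m_sorted, 12), uniq)]
    return(setNames(lab, names(m_sorted))[names(groups)])
  }

  mse <- sse / df_err
  nh <- k / sum(1 / ni)  # harmonic mean for unequal group sizes
  se_mean <- sqrt(mse / nh)

  # ns[i, j]: the stretch of sorted means i..j is not significantly spread
  ns <- diag(TRUE, k)
  for (span in k:2) {
    rp <- qtukey((1 - alpha)^(span - 1), span, df_err) * se_mean
    for (i in seq_len(k - span + 1L)) {
      j <- i + span - 1L
      if (ns[i, j]) next  # already inside a non-significant range
      if (m_sorted[i] - m_sorted[j] <= rp) {
        for (a in i:j) for (b in a:j) ns[a, b] <- TRUE
      }
    }
  }

  # maximal non-significant intervals -> letters
  intervals <- list()
  for (i in seq_len(k)) {
    j <- max(which(ns[i, i:k])) + i - 1L
    intervals[[i]] <- c(i, j)
  }
  keep <- !vapply(seq_len(k), function(i) {
    any(vapply(seq_len(k)[-i], function(l)
      intervals[[l]][1] <= intervals[[i]][1] &&
        intervals[[l]][2] >= intervals[[i]][2], logical(1)))
  }, logical(1))
  intervals <- unique(intervals[keep])

  lab <- rep("", k)
  for (t in seq_along(intervals)) {
    iv <- intervals[[t]]
    for (i in iv[1]:iv[2]) lab[i] <- paste0(lab[i], letters[t])
  }
  setNames(lab, names(m_sorted))[names(groups)]
}

#' Write the RQ table as TSV
#'
#' @param rq An `rq_result` from [delta_delta_ct()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_rq_table <- function(rq, path) {
  stopifnot(inherits(rq, "rq_result"))
  out <- as.data.frame(rq)
  out$mean_dct <- round(out$mean_dct, 4)
  out$ddct <- round(out$ddct, 4)
  out$rq <- round(out$rq, 4)
  out$se <- round(out$se, 4)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
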