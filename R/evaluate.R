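# Evaluation: voxel confusion counts within the EZ VOI, sensitivity /
# specificity / balanced accuracy, cohort summaries, correlation with
# confidence interval, Bland-Altman agreement, and the two-group t-test.

#' Voxel confusion counts restricted to the VOI
#'
#' @param pred,truth [voxel_mask]s (or 3D logical arrays) of identical shape.
#' @param voi [voxel_mask] delimiting the EZ slab; counts consider VOI voxels
#'   only, since classification is defined only there.
#' @return Named integer vector `(tp, fp, tn, fn)` summing to the VOI size.
#' @export
confusion <- function(pred, truth, voi) {
  g <- function(m) if (inherits(m, "voxel_mask")) m$values else m
  p <- g(pred); t <- g(truth); v <- g(voi)
  if (!all(dim(p) == dim(t)) || !all(dim(p) == dim(v)))
    stop("pred, truth and voi shapes differ")
  p <- p[v]; t <- t[v]
  c(tp = sum(p & t), fp = sum(p & !t), tn = sum(!p & !t), fn = sum(!p & t))
}

#' Sensitivity, specificity and balanced accuracy rate (percent)
#'
#' `SEN = 100 TP / (TP + FN)`, `SPE = 100 TN / (TN + FP)`,
#' `BAR = (SEN + SPE) / 2`. A metric whose denominator is zero (e.g. SEN on an
#' eye with no true disruption) is returned as `NA` rather than an error; only
#' when both denominators vanish is the input rejected.
#'
#' @param tp,fp,tn,fn non-negative counts.
#' @return Named numeric vector `(sen, spe, bar)` in percent.
#' @export
sen_spe_bar <- function(tp, fp, tn, fn) {
  if (tp + fn == 0 && tn + fp == 0)
    stop("no voxels to evaluate: both denominators are zero")
  sen <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  spe <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
  bar <- if (!is.na(sen) && !is.na(spe)) (sen + spe) / 2 else NA_real_
  c(sen = sen, spe = spe, bar = bar)
}

#' Cohort mean, standard deviation and 95% confidence interval
#'
#' The interval is `mean +/- t(0.975, n-1) * sd / sqrt(n)`.
#'
#' @param values numeric vector, `n >= 2`.
#' @return List with `mean`, `sd`, `ci` (length-2), `n`.
#' @export
cohort_stats <- function(values) {
  n <- length(values)
  if (n < 2L) stop("need at least 2 values")
  m <- mean(values); s <- sd(values)
  half <- qt(0.975, n - 1L) * s / sqrt(n)
  list(mean = m, sd = s, ci = c(m - half, m + half), n = n)
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' @param x,y numeric vectors of equal length, `n >= 4`, each with positive
#'   variance.
#' @return List with `r`, `ci` (95%, Fisher z-transform) and two-sided `p`
#'   from the t distribution.
#' @export
correlation_with_ci <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 4L) stop("need at least 4 pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance in x or y")
  ct <- cor.test(x, y, method = "pearson", conf.level = 0.95)
  list(r = unname(ct$estimate), ci = as.numeric(ct$conf.int), p = ct$p.value)
}

#' Bland-Altman agreement analysis
#'
#' Differences `d = x - y`; limits of agreement `mean(d) +/- 1.96 sd(d)`.
#'
#' @param x,y paired measurements (e.g. detected and ground-truth volumes).
#' @return List with `mean_diff`, `lower`, `upper`, and a plotting `table`
#'   (columns `mean`, `diff`).
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 2L) stop("need at least 2 pairs")
  d <- x - y
  md <- mean(d); s <- sd(d)
  list(mean_diff = md, lower = md - 1.96 * s, upper = md + 1.96 * s,
       table = data.frame(mean = (x + y) / 2, diff = d))
}

#' Two-sample Student's t-test (pooled variance)
#'
#' @param a,b numeric groups, each `n >= 2`.
#' @param welch use the Welch (unequal-variance) form instead.
#' @return List with `t` and two-sided `p`.
#' @export
two_sample_ttest <- function(a, b, welch = FALSE) {
  if (length(a) < 2L || length(b) < 2L) stop("each group needs at least 2 values")
  if (sd(a) == 0 && sd(b) == 0 && mean(a) == mean(b))
    return(list(t = 0, p = 1))
  tt <- t.test(a, b, var.equal = !welch)
  list(t = unname(tt$statistic), p = tt$p.value)
}

#' Build a per-eye evaluation report
#'
#' Combines voxel confusion metrics and physical disruption volumes per eye
#' with cohort summaries, correlation, Bland-Altman limits, and the
#' trauma-vs-normal t-test.
#'
#' @param per_eye list of per-eye lists with `id`, `group`, counts `tp`, `fp`,
#'   `tn`, `fn`, `detected_volume`, `truth_volume`, `ez_volume`.
#' @return List of class `ez_eval_report` with a per-eye data frame and cohort
#'   summaries.
#' @export
eval_report <- function(per_eye) {
  df <- do.call(rbind, lapply(per_eye, function(e) {
    met <- sen_spe_bar(e$tp, e$fp, e$tn, e$fn)
    data.frame(id = e$id, group = e$group,
               tp = e$tp, fp = e$fp, tn = e$tn, fn = e$fn,
               sen = met[["sen"]], spe = met[["spe"]], bar = met[["bar"]],
               detected_volume = e$detected_volume,
               truth_volume = e$truth_volume,
               ez_volume = e$ez_volume)
  }))
  trauma <- df[df$group == "trauma", ]
  normal <- df[df$group == "normal", ]
  summaries <- list()
  if (nrow(trauma) >= 2L) {
    summaries$trauma_detected_volume <- cohort_stats(trauma$detected_volume)
    summaries$trauma_sen <- cohort_stats(trauma$sen)
    summaries$trauma_spe <- cohort_stats(trauma$spe)
    summaries$trauma_bar <- cohort_stats(trauma$bar)
  }
  if (nrow(normal) >= 2L) {
    summaries$normal_detected_volume <- cohort_stats(normal$detected_volume)
    summaries$normal_spe <- cohort_stats(normal$spe)
  }
  if (nrow(trauma) >= 4L)
    summaries$volume_correlation <- tryCatch(
      correlation_with_ci(trauma$detected_volume, trauma$truth_volume),
      error = function(e) list(r = NA_real_, ci = c(NA_real_, NA_real_),
                               p = NA_real_, note = conditionMessage(e)))
  if (nrow(trauma) >= 2L)
    summaries$bland_altman <-
      bland_altman(trauma$detected_volume, trauma$truth_volume)
  if (nrow(trauma) >= 2L && nrow(normal) >= 2L)
    summaries$group_ttest <- tryCatch(
      two_sample_ttest(trauma$detected_volume, normal$detected_volume),
      error = function(e) list(t = NA_real_, p = NA_real_,
                               note = conditionMessage(e)))
  structure(list(per_eye = df, summaries = summaries), class = "ez_eval_report")
}

#' @export
print.ez_eval_report <- function(x, ...) {
  cat("<ez_eval_report>\n")
  print(x$per_eye, row.names = FALSE)
  s <- x$summaries
  if (!is.null(s$trauma_bar))
    cat(sprintf("trauma: SEN %.2f%% SPE %.2f%% BAR %.2f%%\n",
                s$trauma_sen$mean, s$trauma_spe$mean, s$trauma_bar$mean))
  if (!is.null(s$normal_spe))
    cat(sprintf("normal: SPE %.2f%%\n", s$normal_spe$mean))
  if (!is.null(s$volume_correlation))
    cat(sprintf("detected vs truth volume: r = %.4f (p = %.3g)\n",
                s$volume_correlation$r, s$volume_correlation$p))
  if (!is.null(s$group_ttest))
    cat(sprintf("trauma vs normal volume t-test: t = %.3f, p = %.3g\n",
                s$group_ttest$t, s$group_ttest$p))
  invisible(x)
}

#' Plot agreement diagnostics for an evaluation report
#'
#' Writes a detected-vs-truth scatter plot and a Bland-Altman plot for the
#' trauma eyes as PNG files.
#'
#' @param report an `ez_eval_report`.
#' @param out_dir output directory.
#' @return Invisibly, the paths written.
#' @export
plot_report <- function(report, out_dir) {
  stopifnot(inherits(report, "ez_eval_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tr <- report$per_eye[report$per_eye$group == "trauma", ]
  if (nrow(tr) < 2L) return(invisible(character()))
  scatter <- file.path(out_dir, "volume_scatter.png")
  grDevices::png(scatter, width = 600, height = 600)
  graphics::plot(tr$truth_volume, tr$detected_volume,
                 xlab = "ground-truth disruption volume (mm^3)",
                 ylab = "detected disruption volume (mm^3)",
                 pch = 19, main = "Detected vs ground-truth volume")
  graphics::abline(0, 1, lty = 2)
  grDevices::dev.off()
  ba <- bland_altman(tr$detected_volume, tr$truth_volume)
  ba_path <- file.path(out_dir, "bland_altman.png")
  grDevices::png(ba_path, width = 600, height = 600)
  graphics::plot(ba$table$mean, ba$table$diff,
                 xlab = "mean of detected and truth (mm^3)",
                 ylab = "detected - truth (mm^3)",
                 pch = 19, main = "Bland-Altman agreement")
  graphics::abline(h = c(ba$mean_diff, ba$lower, ba$upper),
                   lty = c(1, 2, 2))
  grDevices::dev.off()
  invisible(c(scatter = scatter, bland_altman = ba_path))
}
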