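#' Anterior-posterior position codings for channels and regions
#'
#' The statistics stage codes the midline source/SO channels Fz, Cz, Pz,
#' POz and the regions F, C, P, O as integers 1-4 from anterior to
#' posterior; distances between them are unit steps along this axis.
#'
#' @param x channel label (Fz/Cz/Pz/POz) or region letter (F/C/P/O).
#' @return integer position 1-4.
#' @export
#' @examples
#' channel_position("Cz")   # 2
#' region_position("O")     # 4
channel_position <- function(x) {
  pos <- region_scheme()$sources
  out <- pos[x]
  if (anyNA(out)) stop("unknown source/SO channel: ",
                       paste(x[is.na(out)], collapse = ", "))
  unname(out)
}

#' @rdname channel_position
#' @export
region_position <- function(x) {
  pos <- region_scheme()$regions
  out <- pos[x]
  if (anyNA(out)) stop("unknown region: ", paste(x[is.na(out)], collapse = ", "))
  unname(out)
}

#' Distance predictors of the flow-peak models
#'
#' `d_source_so` is the anterior-posterior distance between the flow source
#' channel and the SO channel (0-3); `d_sink_so` between the sink region
#' and the SO channel (0-3); `d_source_sink` between the source channel and
#' the sink region (0-3; >= 1 when the sink is not the source's own
#' region); `relative_distance` is `d_sink_so - d_source_so`, positive when
#' the source is closer to the SO channel than the sink is.
#'
#' @param source source channel label (Fz/Cz/Pz/POz).
#' @param so_channel SO channel label (Fz/Cz/Pz/POz).
#' @param sink sink region letter (F/C/P/O).
#' @return integer distance (vectorised).
#' @export
#' @examples
#' relative_distance("O", "Fz", "Cz")  # +1
d_source_so <- function(source, so_channel)
  abs(channel_position(source) - channel_position(so_channel))

#' @rdname d_source_so
#' @export
d_sink_so <- function(sink, so_channel)
  abs(region_position(sink) - channel_position(so_channel))

#' @rdname d_source_so
#' @export
d_source_sink <- function(source, sink)
  abs(region_position(sink) - channel_position(source))

#' @rdname d_source_so
#' @export
relative_distance <- function(sink, source, so_channel)
  d_sink_so(sink, so_channel) - d_source_so(source, so_channel)

#' Exclude values outside mean +/- 2 SD
#'
#' The outlier rule applied before every statistical test: values outside
#' the boundary mean +/- 2 standard deviations (computed once, no
#' iteration) are dropped.
#'
#' @param values numeric vector (>= 3 values).
#' @return list with `kept` (retained values), `keep` (logical along the
#'   input), `n_dropped` and `bounds`.
#' @export
exclude_outliers <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 3) stop("need at least 3 values for the outlier rule")
  m <- mean(values); s <- stats::sd(values)
  keep <- values >= m - 2 * s & values <= m + 2 * s
  list(kept = values[keep], keep = keep, n_dropped = sum(!keep),
       bounds = c(lower = m - 2 * s, upper = m + 2 * s))
}

.sig_tier <- function(p) {
  ifelse(p < 0.005, "strong", ifelse(p < 0.05, "significant",
                                     ifelse(p < 0.1, "marginal", "ns")))
}

#' Compare SO-phase outflow with non-SO windows
#'
#' One-way ANOVA of per-subject outflow across the six conditions (the five
#' canonical SO phases -pi, -pi/2, 0, pi/2, pi plus non-SO windows),
#' followed by Tukey-adjusted post hoc comparisons of each phase against
#' the non-SO condition. Significance tiers: strong (< 0.005), significant
#' (< 0.05), marginal (< 0.1).
#'
#' @param data data frame with columns `subject`, `condition` (factor or
#'   character; the non-SO level named `"nonSO"`) and `value`.
#' @param outliers apply [exclude_outliers] within each condition first.
#' @return object of class `so_stats`: list with `model` id, `anova`
#'   (F statistic, p value), `comparisons` (pair, p_adj, tier) and
#'   `correction`.
#' @export
compare_so_vs_nonso <- function(data, outliers = TRUE) {
  stopifnot(all(c("subject", "condition", "value") %in% names(data)))
  if (length(unique(data$subject)) < 3)
    stop("need at least 3 subjects")
  if (outliers) {
    keep <- unlist(lapply(split(seq_len(nrow(data)), data$condition),
                          function(i) i[exclude_outliers(data$value[i])$keep]))
    data <- data[sort(keep), ]
  }
  data$condition <- factor(data$condition)
  fit <- stats::aov(value ~ condition, data = data)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$condition
  pairs <- rownames(tk)
  sel <- grepl("nonSO", pairs)
  comp <- data.frame(pair = pairs[sel], p_adj = tk[sel, "p adj"],
                     tier = .sig_tier(tk[sel, "p adj"]),
                     row.names = NULL)
  structure(list(model = "so_vs_nonso_anova",
                 anova = c(F = an[1, "F value"], p = an[1, "Pr(>F)"]),
                 comparisons = comp, correction = "tukey"),
            class = "so_stats")
}

#' @export
print.so_stats <- function(x, ...) {
  cat("Model:", x$model, "\n")
  if (!is.null(x$anova))
    cat("ANOVA: F =", format(x$anova["F"], digits = 4),
        ", p =", format(x$anova["p"], digits = 3), "\n")
  if (!is.null(x$coefficients)) {
    cat("Fixed effects:\n")
    print(x$coefficients, digits = 3)
  }
  if (!is.null(x$comparisons)) {
    cat("Comparisons (", x$correction, "-adjusted):\n", sep = "")
    print(x$comparisons, digits = 3)
  }
  if (!is.null(x$groups)) {
    cat("Per-group regressions (", x$correction, "-adjusted):\n", sep = "")
    print(x$groups, digits = 3)
  }
  invisible(x)
}

#' Mixed-effects model of flow peak heights
#'
#' Fits `peak height ~ fixed terms + (1 | subject)` by REML
#' (random intercept per participant) and reports the fixed-effect
#' coefficients with Satterthwaite p values. The fixed terms are the
#' integer codings of the peak-table columns: `source_idx`,
#' `so_channel_idx`, `d_source_so`, `phase_code` (prepeak = 1,
#' postpeak = 2), `d_sink_so`, `d_source_sink`, `cluster_code` (Global = 1,
#' Local = 2), `coupling_code` (noncoupled = 1, coupled = 2),
#' `so_amplitude`.
#'
#' @param peak_table data frame with a `subject` column, the response and
#'   the requested fixed-term columns.
#' @param fixed_terms character vector of column names to enter as fixed
#'   effects.
#' @param response response column name (default `"peak_value"`).
#' @param outliers apply [exclude_outliers] to the response first.
#' @return `so_stats` object with a `coefficients` data frame (term,
#'   estimate, p).
#' @export
peak_height_lme <- function(peak_table, fixed_terms,
                            response = "peak_value", outliers = TRUE) {
  stopifnot(all(c("subject", response, fixed_terms) %in% names(peak_table)))
  if (length(unique(peak_table$subject)) < 2)
    stop("need at least 2 subjects for a random intercept")
  for (tm in fixed_terms)
    if (length(unique(peak_table[[tm]])) < 2)
      stop("fixed term with a single level: ", tm)
  if (outliers)
    peak_table <- peak_table[exclude_outliers(peak_table[[response]])$keep, ]
  X <- stats::model.matrix(
    stats::reformulate(fixed_terms), data = peak_table)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("rank-deficient design; collinear terms: ",
         paste(colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]], collapse = ", "))
  form <- stats::as.formula(paste(response, "~",
                                  paste(fixed_terms, collapse = " + "),
                                  "+ (1 | subject)"))
  fit <- lmerTest::lmer(form, data = peak_table, REML = TRUE)
  sm <- summary(fit)$coefficients
  coefs <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                      p = sm[, "Pr(>|t|)"], row.names = NULL)
  structure(list(model = "peak_height_lme", coefficients = coefs,
                 fit = fit, correction = "none"),
            class = "so_stats")
}

#' Distance-stratified regressions of behavioural improvement on flow
#'
#' Within each condition group (e.g. the four values of the source-SO
#' distance), averages the post-peak flow per subject, regresses the
#' word-pair-association improvement ratio on that average, and reports
#' the Pearson r and p value per group with a multiple-comparison
#' adjustment across the family of groups (Bonferroni by default; FDR for
#' the source-by-SO-channel grid variant).
#'
#' @param flow data frame with columns `subject`, `group`, `value`
#'   (post-peak flow; multiple rows per subject and group are averaged).
#' @param behavior data frame with columns `subject` and `improvement`.
#' @param correction `"bonferroni"` or `"fdr"`.
#' @param outliers apply [exclude_outliers] to the per-subject averages
#'   within each group.
#' @return `so_stats` object with a `groups` data frame (group, n, r,
#'   p_raw, p_adjusted, tier). Groups with fewer than 3 subjects are
#'   skipped with a warning.
#' @export
wpa_regressions <- function(flow, behavior, correction = c("bonferroni", "fdr"),
                            outliers = TRUE) {
  correction <- match.arg(correction)
  stopifnot(all(c("subject", "group", "value") %in% names(flow)),
            all(c("subject", "improvement") %in% names(behavior)))
  agg <- stats::aggregate(value ~ subject + group, data = flow, FUN = mean)
  rows <- list()
  for (g in unique(agg$group)) {
    sub <- merge(agg[agg$group == g, ], behavior, by = "subject")
    if (outliers && nrow(sub) >= 3)
      sub <- sub[exclude_outliers(sub$value)$keep, ]
    if (nrow(sub) < 3) {
      warning("group ", g, " skipped: fewer than 3 subjects")
      next
    }
    r <- stats::cor(sub$value, sub$improvement)
    p <- if (abs(r) >= 1) 0 else
      stats::cor.test(sub$value, sub$improvement)$p.value
    rows[[length(rows) + 1L]] <- data.frame(group = g, n = nrow(sub),
                                            r = r, p_raw = p)
  }
  if (!length(rows)) stop("no group had enough subjects")
  res <- do.call(rbind, rows)
  res$p_adjusted <- stats::p.adjust(res$p_raw,
                                    method = if (correction == "fdr") "BH"
                                             else "bonferroni")
  res$tier <- .sig_tier(res$p_adjusted)
  structure(list(model = "wpa_regression", groups = res,
                 correction = correction),
            class = "so_stats")
}
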