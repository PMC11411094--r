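#' Remaining-hours matrix (indicators x subjects)
#'
#' @param df Long data frame with columns `subject_id`, `indicator`,
#'   `hours` (`NA` for no-signal cases).
#' @param indicators Row order (default SMA, MAD, MACD, RSI).
#' @return Numeric matrix, rows = indicators, columns = subjects.
#' @export
remaining_matrix <- function(df,
                             indicators = c("SMA", "MAD", "MACD", "RSI")) {
  stopifnot(all(c("subject_id", "indicator", "hours") %in% names(df)))
  subjects <- unique(df$subject_id)
  m <- matrix(NA_real_, nrow = length(indicators), ncol = length(subjects),
              dimnames = list(indicators, subjects))
  for (i in seq_len(nrow(df))) {
    if (df$indicator[i] %in% indicators) {
      m[df$indicator[i], as.character(df$subject_id[i])] <- df$hours[i]
    }
  }
  if (any(m < 0, na.rm = TRUE)) {
    stop("remaining hours must be non-negative", call. = FALSE)
  }
  m
}

#' Remaining-hours table of the six-cow calving study
#'
#' Loads the published remaining-time observations (hours from each
#' indicator's turning-point signal to calving, by cow) that the original
#' six-cow Holter feasibility study reported; the RSI cell of cow h055 is
#' missing because its monotonically declining trend produced no RSI
#' signal.
#'
#' @return Numeric matrix: rows SMA, MAD, MACD, RSI; columns the six cows.
#' @export
calving_study_hours <- function() {
  path <- system.file("extdata", "calving_study_remaining_hours.csv",
                      package = "calvetrend", mustWork = TRUE)
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Marginal summaries of a remaining-hours matrix
#'
#' Mean and sample standard deviation (n-1 denominator) per indicator row
#' (across subjects) and per subject column (across indicators), omitting
#' missing cells. A marginal with a single value has no sd.
#'
#' @param m Matrix from [remaining_matrix()].
#' @return A list of class `remaining_summary` with data frames `rows`
#'   and `cols` (`mean`, `sd`, `n`).
#' @export
summarize_remaining <- function(m) {
  stopifnot(is.matrix(m))
  marg <- function(x) {
    x <- x[!is.na(x)]
    c(mean = if (length(x)) mean(x) else NA_real_,
      sd = if (length(x) >= 2) stats::sd(x) else NA_real_,
      n = length(x))
  }
  rows <- t(apply(m, 1, marg))
  cols <- t(apply(m, 2, marg))
  structure(list(rows = data.frame(indicator = rownames(m), rows,
                                   row.names = NULL),
                 cols = data.frame(subject_id = colnames(m), cols,
                                   row.names = NULL)),
            class = "remaining_summary")
}

#' Coefficient of variation, percent
#'
#' `100 * sd / mean` over the non-missing values.
#'
#' @param values Numeric vector, at least two non-missing values with a
#'   positive mean.
#' @return CV in percent.
#' @export
cv_percent <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) {
    stop("need at least two values for a coefficient of variation",
         call. = FALSE)
  }
  if (mean(values) <= 0) stop("mean must be positive", call. = FALSE)
  100 * stats::sd(values) / mean(values)
}

#' Omnibus comparison of indicators' remaining times
#'
#' Compares the remaining times of MAD, MACD and RSI across subjects,
#' treating subject as a blocking/random factor. With
#' `exclude_incomplete = TRUE` (default), subjects missing any of the
#' three signals are dropped and the balanced design is analysed as a
#' randomized complete block ANOVA (identical to the mixed model with
#' subject random intercepts for balanced data); otherwise all available
#' cells enter a linear mixed model (`lme4::lmer`) and the indicator F is
#' combined with containment degrees of freedom.
#'
#' @param m Remaining-hours matrix.
#' @param indicators Indicators compared (default MAD, MACD, RSI).
#' @param exclude_incomplete Drop subjects with any missing cell.
#' @return A list of class `indicator_comparison` with `F`, `p`, `df`,
#'   `method`, `n_subjects`, `degenerate`.
#' @export
omnibus_compare <- function(m, indicators = c("MAD", "MACD", "RSI"),
                            exclude_incomplete = TRUE) {
  stopifnot(is.matrix(m), all(indicators %in% rownames(m)))
  sub <- m[indicators, , drop = FALSE]
  if (exclude_incomplete) {
    sub <- sub[, colSums(is.na(sub)) == 0, drop = FALSE]
    if (ncol(sub) < 2) {
      stop("need at least two subjects with complete signal triples",
           call. = FALSE)
    }
    long <- data.frame(
      hours = as.vector(sub),
      indicator = factor(rep(rownames(sub), times = ncol(sub))),
      subject = factor(rep(colnames(sub), each = nrow(sub))))
    fit <- stats::aov(hours ~ indicator + subject, data = long)
    tab <- summary(fit)[[1]]
    rn <- trimws(rownames(tab))
    ms_res <- tab[rn == "Residuals", "Mean Sq"]
    degenerate <- !is.finite(ms_res) || ms_res <= .Machine$double.eps^0.5
    Fval <- if (degenerate) NA_real_ else tab[rn == "indicator", "F value"]
    pval <- if (degenerate) NA_real_ else tab[rn == "indicator", "Pr(>F)"]
    df <- c(length(indicators) - 1L,
            (length(indicators) - 1L) * (ncol(sub) - 1L))
    structure(list(F = unname(Fval), p = unname(pval), df = df,
                   method = "randomized complete block ANOVA",
                   n_subjects = ncol(sub), degenerate = degenerate),
              class = "indicator_comparison")
  } else {
    keep <- !is.na(sub)
    long <- data.frame(
      hours = as.vector(sub)[as.vector(keep)],
      indicator = factor(rep(rownames(sub), times = ncol(sub))[as.vector(keep)]),
      subject = factor(rep(colnames(sub), each = nrow(sub))[as.vector(keep)]))
    if (nlevels(long$subject) < 2) {
      stop("need at least two subjects", call. = FALSE)
    }
    fit <- lme4::lmer(hours ~ indicator + (1 | subject), data = long,
                      REML = TRUE)
    a <- stats::anova(fit)
    Fval <- a["indicator", "F value"]
    df1 <- a["indicator", "npar"]
    if (is.null(df1) || is.na(df1)) df1 <- length(indicators) - 1L
    # containment denominator df: N - #indicators - #subjects + 1
    df2 <- nrow(long) - length(indicators) - nlevels(long$subject) + 1L
    pval <- stats::pf(Fval, df1, df2, lower.tail = FALSE)
    structure(list(F = unname(Fval), p = unname(pval), df = c(df1, df2),
                   method = "linear mixed model (subject random intercept)",
                   n_subjects = nlevels(long$subject), degenerate = FALSE),
              class = "indicator_comparison")
  }
}

#' Paired comparison of two indicators
#'
#' Paired analysis of the remaining times of one indicator pair across
#' subjects: `F` is the squared paired t statistic (equivalent to the
#' two-level mixed model for two treatments), with p from `F(1, n-1)`.
#' With `complete_triples = TRUE` only subjects with all of MAD, MACD and
#' RSI present are used; otherwise all subjects with both members of the
#' pair.
#'
#' @param m Remaining-hours matrix.
#' @param pair Character vector of two indicator names.
#' @param complete_triples Restrict to complete-triple subjects.
#' @param triple Indicators defining completeness.
#' @return A list of class `pairwise_comparison`: `pair`, `n`,
#'   `mean_diff`, `sd_diff`, `F`, `p`, `degenerate`.
#' @export
pairwise_compare <- function(m, pair, complete_triples = FALSE,
                             triple = c("MAD", "MACD", "RSI")) {
  stopifnot(is.matrix(m), length(pair) == 2, all(pair %in% rownames(m)))
  cols <- if (complete_triples) {
    colSums(is.na(m[triple, , drop = FALSE])) == 0
  } else {
    colSums(is.na(m[pair, , drop = FALSE])) == 0
  }
  d <- m[pair[1], cols] - m[pair[2], cols]
  n <- length(d)
  if (n < 2) {
    stop("need at least two subjects with both indicators", call. = FALSE)
  }
  md <- mean(d)
  sdd <- stats::sd(d)
  if (sdd == 0) {
    warning("zero variance of paired differences; F is degenerate",
            call. = FALSE)
    return(structure(list(pair = pair, n = n, mean_diff = md, sd_diff = 0,
                          F = if (md == 0) NA_real_ else Inf, p = NA_real_,
                          degenerate = TRUE),
                     class = "pairwise_comparison"))
  }
  tstat <- md / (sdd / sqrt(n))
  Fval <- tstat^2
  structure(list(pair = pair, n = n, mean_diff = md, sd_diff = sdd,
                 F = Fval, p = stats::pf(Fval, 1, n - 1, lower.tail = FALSE),
                 degenerate = FALSE),
            class = "pairwise_comparison")
}

#' All pairwise indicator comparisons with Bonferroni threshold
#'
#' Runs [pairwise_compare()] for MAD-MACD, MAD-RSI and MACD-RSI and
#' attaches the Bonferroni-adjusted significance level 0.05/3.
#'
#' @inheritParams pairwise_compare
#' @return A list with `pairs` (the three `pairwise_comparison` results)
#'   and `alpha_adjusted`.
#' @export
pairwise_all <- function(m, complete_triples = FALSE) {
  prs <- list(c("MAD", "MACD"), c("MAD", "RSI"), c("MACD", "RSI"))
  res <- lapply(prs, function(p) {
    pairwise_compare(m, p, complete_triples = complete_triples)
  })
  names(res) <- vapply(prs, paste, collapse = "-", FUN.VALUE = "")
  list(pairs = res, alpha_adjusted = 0.05 / 3)
}

#' Score turning-point recovery against ground truth
#'
#' @param detected Detected turning times (hours), `NA` where no signal
#'   was found; or a list of `turning_point` objects.
#' @param truth True turning times (hours), one per replicate.
#' @param tolerance Absolute error tolerated (hours, default 2).
#' @return A list of class `recovery_report`: per-replicate signed
#'   `errors` (detected - truth), `bias`, `rmse`, `prop_within`
#'   (proportion of all replicates detected within tolerance; no-signal
#'   replicates count as failures), `n`, `n_not_found`, `tolerance`.
#' @export
recovery <- function(detected, truth, tolerance = 2) {
  if (is.list(detected) && length(detected) &&
      inherits(detected[[1]], "turning_point")) {
    detected <- vapply(detected, function(s) {
      if (s$found) s$signal_time else NA_real_
    }, numeric(1))
  }
  detected <- as.numeric(detected)
  truth <- as.numeric(truth)
  if (length(detected) != length(truth)) {
    stop("detected and truth must have the same length", call. = FALSE)
  }
  err <- detected - truth
  found <- !is.na(detected)
  structure(list(
    errors = err,
    bias = if (any(found)) mean(err[found]) else NA_real_,
    rmse = if (any(found)) sqrt(mean(err[found]^2)) else NA_real_,
    prop_within = mean(found & !is.na(err) & abs(err) <= tolerance),
    n = length(truth),
    n_not_found = sum(!found),
    tolerance = tolerance
  ), class = "recovery_report")
}

#' Replicated turning-point recovery study on synthetic recordings
#'
#' Generates `n_rep` synthetic recordings from `base_spec` (optionally
#' drawing the turning offset per replicate from a uniform range), runs
#' the composite series through STL decomposition, computes the indicator
#' panel on the trend, detects each indicator's turning point, and scores
#' recovery against the known truth.
#'
#' Replicate seeds are derived deterministically from `seed`. By default
#' the pipeline starts from the noise-bearing 30-min composite (trend +
#' daily cycle + AR(1) remainder); `level = "beats"` additionally runs
#' beat generation, the 30% outlier filter, binning and imputation.
#'
#' @param n_rep Number of replicates.
#' @param base_spec A [synthetic_spec()]; its seed field is overridden
#'   per replicate.
#' @param indicators Indicators to detect on.
#' @param mode `"retrospective"` or `"online"` detection.
#' @param k Confirmation lag for online detection.
#' @param tolerance Recovery tolerance in hours.
#' @param turning_offset_range Optional `c(lo, hi)`; when given, each
#'   replicate's `turning_offset` is drawn uniformly from it.
#' @param level `"composite"` (default) or `"beats"`.
#' @param seed Master seed for replicate seeds and offset draws.
#' @return A list of class `recovery_study` with `results` (long data
#'   frame: replicate, indicator, found, detected, truth, remaining
#'   hours), `reports` (per-indicator `recovery_report`), `n_rep`,
#'   `seed`.
#' @export
run_recovery_study <- function(n_rep = 100L,
                               base_spec = synthetic_spec(),
                               indicators = "MAD",
                               mode = c("retrospective", "online"),
                               k = 3L,
                               tolerance = 2,
                               turning_offset_range = NULL,
                               level = c("composite", "beats"),
                               seed = 1L) {
  mode <- match.arg(mode)
  level <- match.arg(level)
  offsets <- if (is.null(turning_offset_range)) {
    rep(base_spec$turning_offset, n_rep)
  } else {
    with_rng_seed(seed, stats::runif(n_rep, turning_offset_range[1],
                                     turning_offset_range[2]))
  }
  rep_seeds <- (as.integer(seed) + 17L * seq_len(n_rep)) %% 2147483629L
  rows <- vector("list", n_rep)
  for (i in seq_len(n_rep)) {
    spec_i <- base_spec
    spec_i$turning_offset <- offsets[i]
    spec_i$seed <- rep_seeds[i]
    validate_synthetic_spec(spec_i)
    rec <- if (level == "beats") {
      r <- generate_record(spec_i)
      clean <- filter_outliers(r$beats)$beats
      b <- bin_series(clean, bin_width = spec_i$bin_width,
                      n_bins = nrow(r$components),
                      calving_time = r$calving_time)
      list(binned = impute_gaps(b), truth = ground_truth(r))
    } else {
      comp <- generate_components(spec_i)
      truth <- list(
        true_turning_time = if (spec_i$mode == "rise_decline") {
          spec_i$calving_time - spec_i$turning_offset
        } else NA_real_,
        calving_time = spec_i$calving_time)
      list(binned = composite_series(comp,
                                     calving_time = spec_i$calving_time),
           truth = truth)
    }
    dec <- stl_decompose(rec$binned, period = as.integer(24 / spec_i$bin_width))
    panel <- indicator_panel(dec)
    rows[[i]] <- do.call(rbind, lapply(indicators, function(nm) {
      sig <- if (mode == "retrospective") {
        detect_peak_retrospective(panel[[nm]])
      } else {
        detect_peak_online(panel[[nm]], k = k)
      }
      data.frame(replicate = i, indicator = nm, found = sig$found,
                 detected = if (sig$found) sig$signal_time else NA_real_,
                 truth = rec$truth$true_turning_time,
                 remaining = if (sig$found) {
                   rec$truth$calving_time - sig$signal_time
                 } else NA_real_)
    }))
  }
  results <- do.call(rbind, rows)
  reports <- lapply(indicators, function(nm) {
    sel <- results$indicator == nm
    recovery(results$detected[sel], results$truth[sel],
             tolerance = tolerance)
  })
  names(reports) <- indicators
  structure(list(results = results, reports = reports, n_rep = n_rep,
                 seed = seed),
            class = "recovery_study")
}
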