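# Feature screening: Pearson inter-feature correlation, Kendall association
# with subjective difficulty, and the retained-feature selection step.

#' Pearson correlation coefficient
#'
#' `cov(x, y) / (sd(x) sd(y))`; returns `NA` (not 0) for constant input.
#'
#' @param x,y equal-length numeric vectors (length >= 2).
#' @return correlation in \[-1, 1\] or `NA`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2 || pop_sd(x) == 0 || pop_sd(y) == 0) return(NA_real_)
  mean((x - mean(x)) * (y - mean(y))) / (pop_sd(x) * pop_sd(y))
}

#' Kendall rank correlation (tau-b, tie-corrected)
#'
#' @param x,y equal-length numeric vectors (length >= 2).
#' @return tau-b in \[-1, 1\], or `NA` when either input is all-tied.
#' @export
kendall_tau <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2 || length(unique(x)) < 2 || length(unique(y)) < 2) {
    return(NA_real_)
  }
  suppressWarnings(cor(x, y, method = "kendall"))
}

#' Inter-feature Pearson correlation report
#'
#' @param fm a `pf_feature_matrix`.
#' @param flag_threshold absolute correlation above which a pair is flagged as
#'   redundant.
#' @return object of class `pf_correlation_report`: `matrix` (28 x 28,
#'   symmetric, unit diagonal; `NA` for constant features) and
#'   `pairs_flagged` data.frame.
#' @export
correlation_report <- function(fm, flag_threshold = 0.9) {
  df <- as.data.frame(fm)
  feats <- fm$feature_names
  p <- length(feats)
  m <- diag(1, p)
  dimnames(m) <- list(feats, feats)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      m[i, j] <- m[j, i] <- pearson_r(df[[feats[i]]], df[[feats[j]]])
    }
  }
  flagged <- which(abs(m) > flag_threshold & upper.tri(m), arr.ind = TRUE)
  pairs <- data.frame(feature_a = feats[flagged[, 1]],
                      feature_b = feats[flagged[, 2]],
                      r = m[flagged], stringsAsFactors = FALSE)
  structure(list(matrix = m, pairs_flagged = pairs,
                 flag_threshold = flag_threshold),
            class = "pf_correlation_report")
}

#' Per-behavior mean difficulty ratings
#'
#' @param table a `pf_difficulty` matrix from [load_difficulty_fixture()].
#' @return named numeric vector (one value per behavior), rounded to 2
#'   decimals.
#' @export
mean_difficulty <- function(table) {
  round(colMeans(table), 2)
}

#' Kendall association of every feature with subjective difficulty
#'
#' Each window is assigned its subject's own rating for the window's behavior
#' (`per_subject = TRUE` additionally returns subject-wise taus). Taus are
#' banded as none / moderate / high at the `bands` thresholds.
#'
#' @param fm a `pf_feature_matrix`.
#' @param table a `pf_difficulty` matrix (subjects as rownames).
#' @param bands two |tau| thresholds separating none / moderate / high.
#' @param use_mean_rating use the per-behavior mean rating instead of each
#'   subject's own.
#' @return object of class `pf_difficulty_association`: data.frame `pooled`
#'   (feature, tau, band, sign) and matrix `per_subject` (subjects x features).
#' @export
difficulty_association <- function(fm, table = load_difficulty_fixture(),
                                   bands = c(0.1, 0.3),
                                   use_mean_rating = FALSE) {
  df <- as.data.frame(fm)
  feats <- fm$feature_names
  if (use_mean_rating) {
    means <- mean_difficulty(table)
    diff_val <- means[df$label]
  } else {
    missing_sub <- setdiff(unique(df$subject), rownames(table))
    if (length(missing_sub) > 0) {
      stop("no difficulty ratings for subject(s): ",
           paste(missing_sub, collapse = ", "))
    }
    diff_val <- table[cbind(df$subject, df$label)]
  }
  tau <- vapply(feats, function(f) kendall_tau(df[[f]], diff_val), numeric(1))
  band <- cut(abs(tau), c(-Inf, bands, Inf),
              labels = c("none", "moderate", "high"))
  pooled <- data.frame(feature = feats, tau = tau,
                       band = as.character(band),
                       sign = sign(tau), stringsAsFactors = FALSE)
  excluded <- feats[is.na(tau)]
  subjects <- unique(df$subject)
  per_subject <- matrix(NA_real_, length(subjects), length(feats),
                        dimnames = list(subjects, feats))
  for (s in subjects) {
    sel <- df$subject == s
    for (f in feats) {
      per_subject[s, f] <- kendall_tau(df[[f]][sel], diff_val[sel])
    }
  }
  structure(list(pooled = pooled, per_subject = per_subject,
                 excluded = excluded, bands = bands),
            class = "pf_difficulty_association")
}

#' Select the working feature subset
#'
#' Mode `"paper"` returns the fixed 19-feature set retained after importance
#' screening ([selected_feature_names()]). Mode `"threshold"` drops, from each
#' pair with `|r| > r_threshold`, the member with the lower importance rank
#' (when `importance` is given) or the later one in canonical order.
#'
#' @param fm a `pf_feature_matrix`.
#' @param mode `"paper"` or `"threshold"`.
#' @param r_threshold redundancy threshold for mode `"threshold"`.
#' @param importance optional named importance vector (higher = keep).
#' @return list with `names` (ordered subset) and `matrix` (the reduced
#'   data.frame).
#' @export
select_features <- function(fm, mode = c("paper", "threshold"),
                            r_threshold = 0.9, importance = NULL) {
  mode <- match.arg(mode)
  df <- as.data.frame(fm)
  if (mode == "paper") {
    keep <- selected_feature_names()
  } else {
    rep_ <- correlation_report(fm, flag_threshold = r_threshold)
    drop <- character(0)
    if (nrow(rep_$pairs_flagged) > 0) {
      for (i in seq_len(nrow(rep_$pairs_flagged))) {
        a <- rep_$pairs_flagged$feature_a[i]
        b <- rep_$pairs_flagged$feature_b[i]
        if (a %in% drop || b %in% drop) next
        if (!is.null(importance)) {
          if (!all(c(a, b) %in% names(importance))) stop("unknown feature")
          drop <- c(drop, if (importance[[a]] >= importance[[b]]) b else a)
        } else {
          drop <- c(drop, b)  # later in canonical order
        }
      }
    }
    keep <- setdiff(fm$feature_names, drop)
  }
  list(names = keep,
       matrix = df[, c("subject", "window_start_s", keep, "label")])
}
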