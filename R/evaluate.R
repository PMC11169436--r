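## Identification evaluation protocol: top-K accuracy, CMC curves,
## vendor-pair stratification, score distributions, and the two
## statistical tests used to compare accuracies.

## Rank of each query's true patient under descending similarity with
## ties broken by ascending gallery index (matches rank_gallery()).
true_ranks <- function(S, query_labels, gallery_labels) {
  vapply(seq_len(nrow(S)), function(i) {
    j <- which(gallery_labels == query_labels[i])
    if (!length(j)) return(NA_integer_)
    row <- S[i, ]
    best <- min(vapply(j, function(jj)
      sum(row > row[jj]) + sum(row == row[jj] & seq_along(row) < jj) + 1L, 1L))
    as.integer(best)
  }, 1L)
}

#' Top-K identification accuracy
#'
#' Fraction of queries whose true patient appears among the K
#' highest-similarity gallery entries. Queries whose patient is not
#' enrolled in the gallery are excluded from the proportion, counted, and
#' reported via the `"n_excluded"` attribute (with a warning).
#'
#' @param S `N_q x N_g` similarity matrix.
#' @param query_labels,gallery_labels Patient ids aligned with the rows
#'   and columns of `S`.
#' @param k Rank cutoff `K >= 1`.
#' @return Proportion in `[0, 1]`, with attributes `n_used` and
#'   `n_excluded`.
#' @export
topk_accuracy <- function(S, query_labels, gallery_labels, k = 1) {
  if (k < 1) stop("k must be >= 1")
  r <- true_ranks(S, query_labels, gallery_labels)
  excl <- sum(is.na(r))
  if (excl > 0)
    warning(excl, " quer", if (excl == 1) "y has" else "ies have",
            " no enrolled patient; excluded from the accuracy")
  structure(mean(r <= k, na.rm = TRUE), n_used = sum(!is.na(r)),
            n_excluded = excl)
}

#' Cumulative match characteristic curve
#'
#' `acc@K` for `K = 1 .. K_max`; non-decreasing, and equal to 1 at
#' `K = N_g` when every query's patient is enrolled.
#'
#' @inheritParams topk_accuracy
#' @param k_max Largest rank, `<= N_g`.
#' @return Numeric vector of length `k_max`.
#' @export
cmc_curve <- function(S, query_labels, gallery_labels, k_max = ncol(S)) {
  stopifnot(k_max <= ncol(S), k_max >= 1)
  r <- true_ranks(S, query_labels, gallery_labels)
  vapply(seq_len(k_max), function(k) mean(r <= k, na.rm = TRUE), 0)
}

#' Genuine and impostor similarity-score distributions
#'
#' Splits the similarity matrix into genuine entries (query and gallery
#' from the same patient) and impostor entries (all others) and summarizes
#' each. Also reports whether the distributions overlap (genuine minimum
#' vs impostor maximum).
#'
#' @inheritParams topk_accuracy
#' @return List with means, SDs, counts and the overlap indicator.
#' @export
score_distributions <- function(S, query_labels, gallery_labels) {
  genuine <- outer(query_labels, gallery_labels, "==")
  if (!any(genuine)) stop("no genuine pairs present")
  if (all(genuine)) stop("no impostor pairs present (degenerate setup)")
  g <- S[genuine]; im <- S[!genuine]
  list(genuine_mean = mean(g), genuine_sd = stats::sd(g),
       impostor_mean = mean(im), impostor_sd = stats::sd(im),
       genuine_n = length(g), impostor_n = length(im),
       genuine_min = min(g), impostor_max = max(im),
       separated = min(g) > max(im))
}

#' Vendor-stratified identification report
#'
#' The full evaluation protocol: overall `acc@K`, the CMC curve, per
#' (baseline vendor, follow-up vendor) cell accuracies with their counts,
#' pooled same-vendor and different-vendor groups, genuine/impostor score
#' summaries, and the list of queries failing the top-K criterion with
#' their top scores. A query whose vendor tag (or whose true baseline's
#' tag) is missing is grouped under `"untagged"`, never dropped.
#'
#' @inheritParams topk_accuracy
#' @param query_vendors,gallery_vendors Vendor tags aligned with queries
#'   and gallery entries.
#' @param ks Rank cutoffs to report (default 1 and 10, capped at `N_g`).
#' @param k_alert Rank cutoff defining the error list (alert rule).
#' @return A list of class `eval_report`.
#' @export
stratified_eval <- function(S, query_labels, gallery_labels, query_vendors,
                            gallery_vendors, ks = c(1, 10),
                            k_alert = max(ks)) {
  ks <- ks[ks <= ncol(S)]
  r <- true_ranks(S, query_labels, gallery_labels)
  base_vendor <- vapply(query_labels, function(l) {
    j <- which(gallery_labels == l)[1]
    if (is.na(j)) NA_character_ else gallery_vendors[j]
  }, "")
  qv <- ifelse(is.na(query_vendors), "untagged", query_vendors)
  bv <- ifelse(is.na(base_vendor), "untagged", base_vendor)
  cell <- paste(bv, qv, sep = " -> ")
  group <- ifelse(bv == "untagged" | qv == "untagged", "untagged",
                  ifelse(bv == qv, "same vendor", "different vendors"))

  acc_of <- function(idx) {
    row <- c(n = length(idx))
    for (k in ks) row[paste0("acc", k)] <- mean(r[idx] <= k, na.rm = TRUE)
    row
  }
  cells <- t(vapply(sort(unique(cell)), function(cl) acc_of(which(cell == cl)),
                    acc_of(seq_along(r))))
  groups <- t(vapply(c("same vendor", "different vendors", "untagged"),
                     function(gr) {
                       idx <- which(group == gr)
                       if (!length(idx)) c(n = 0, stats::setNames(
                         rep(NA_real_, length(ks)), paste0("acc", ks)))
                       else acc_of(idx)
                     }, acc_of(seq_along(r))))
  overall <- acc_of(seq_along(r))

  fails <- which(r > k_alert | is.na(r))
  errors <- data.frame(query = fails, patient_id = query_labels[fails],
                       rank = r[fails],
                       top_score = vapply(fails, function(i) max(S[i, ]), 0),
                       group = group[fails])

  structure(list(overall = overall, cells = cells, groups = groups,
                 cmc = cmc_curve(S, query_labels, gallery_labels),
                 scores = score_distributions(S, query_labels, gallery_labels),
                 errors = errors, ks = ks, k_alert = k_alert,
                 n_queries = nrow(S), n_gallery = ncol(S),
                 note = "raw p-values; no multiple-testing adjustment applied"),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d queries vs %d gallery patients\n",
              x$n_queries, x$n_gallery))
  cat("overall: ", paste(sprintf("%s=%.3f", paste0("acc", x$ks),
                                 x$overall[paste0("acc", x$ks)]),
                         collapse = "  "), "\n")
  cat("groups:\n"); print(round(x$groups, 4))
  cat("vendor cells:\n"); print(round(x$cells, 4))
  cat(sprintf("scores: genuine %.3f+-%.3f, impostor %.3f+-%.3f (%s)\n",
              x$scores$genuine_mean, x$scores$genuine_sd,
              x$scores$impostor_mean, x$scores$impostor_sd,
              if (x$scores$separated) "separated" else "overlapping"))
  cat(nrow(x$errors), "quer(ies) beyond rank", x$k_alert, "\n")
  invisible(x)
}

#' Two-proportion Z-test (unpaired)
#'
#' Pooled-variance Z-test comparing `k1/n1` with `k2/n2`:
#' `Z = (p1 - p2) / sqrt(p_hat (1 - p_hat) (1/n1 + 1/n2))` with
#' `p_hat = (k1 + k2) / (n1 + n2)`; two-sided normal p-value.
#'
#' @param k1,n1,k2,n2 Successes and totals of the two groups.
#' @return A list of class `reid_test` with `statistic`, `p_value`,
#'   `method` and the echoed inputs.
#' @export
two_proportion_ztest <- function(k1, n1, k2, n2) {
  stopifnot(n1 >= 1, n2 >= 1, k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2)
  p1 <- k1 / n1; p2 <- k2 / n2
  ph <- (k1 + k2) / (n1 + n2)
  if (ph == 0 || ph == 1) {
    warning("pooled proportion is ", ph, "; zero variance, p set to 1")
    z <- 0; p <- 1
  } else {
    z <- (p1 - p2) / sqrt(ph * (1 - ph) * (1 / n1 + 1 / n2))
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(statistic = z, p_value = p,
                 method = "two-proportion Z-test (pooled, two-sided)",
                 inputs = list(k1 = k1, n1 = n1, k2 = k2, n2 = n2)),
            class = "reid_test")
}

#' McNemar's chi-squared test on discordant pairs
#'
#' Compares two paired proportions through the discordant-pair counts `b`
#' and `c`. The default statistic uses the continuity correction,
#' `chi^2 = (|b - c| - 1)^2 / (b + c)` on 1 df; the uncorrected variant is
#' reported alongside. `exact = TRUE` (the default when `b + c < 25`)
#' additionally reports the exact binomial p-value.
#'
#' @param b,c Discordant-pair counts.
#' @param correction Use the continuity-corrected statistic as primary.
#' @param exact Report the exact binomial p-value; `NULL` = auto
#'   (`b + c < 25`).
#' @return A list of class `reid_test`.
#' @export
mcnemar_test <- function(b, c, correction = TRUE, exact = NULL) {
  stopifnot(b >= 0, c >= 0)
  if (b + c == 0) stop("no discordant pairs (b + c = 0); test undefined")
  chi_corr <- (abs(b - c) - 1)^2 / (b + c)
  chi_raw <- (b - c)^2 / (b + c)
  chi <- if (correction) chi_corr else chi_raw
  p <- stats::pchisq(chi, df = 1, lower.tail = FALSE)
  if (is.null(exact)) exact <- (b + c) < 25
  p_exact <- if (exact) stats::binom.test(b, b + c, 0.5)$p.value else NA_real_
  structure(list(statistic = chi, p_value = p,
                 statistic_uncorrected = chi_raw,
                 p_value_uncorrected = stats::pchisq(chi_raw, 1, lower.tail = FALSE),
                 p_value_exact = p_exact,
                 method = paste0("McNemar's chi-squared test",
                                 if (correction) " (continuity-corrected)"),
                 inputs = list(b = b, c = c)),
            class = "reid_test")
}

#' @export
print.reid_test <- function(x, ...) {
  cat(sprintf("%s\nstatistic = %.4f, p = %.4g\n", x$method, x$statistic,
              x$p_value))
  invisible(x)
}
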