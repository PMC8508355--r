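# Post-hoc feature statistics: correlation with the Ki-67 labelling index
# and with positive-cell density, histology-independence testing, and
# Benjamini-Hochberg multiplicity control. Analyses run on the feature set
# surviving the preliminary (constant + perfect-correlation) filters only.

#' Pearson correlation test
#'
#' @param x,y numeric vectors, `n >= 3`.
#' @return list with `r` and two-sided `p` from the t transform with n-2
#'   degrees of freedom; zero-variance input gives `r = NA` and
#'   `degenerate = TRUE`.
#' @export
pearson_test <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0 || sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, degenerate = TRUE))
  n <- length(x)
  r <- cor(x, y)
  r <- min(max(r, -1), 1)
  if (abs(r) == 1) return(list(r = r, p = 0, degenerate = FALSE))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(t), n - 2), degenerate = FALSE)
}

# exact two-sided p for U by enumeration of all group-A rank subsets
.mw_exact_p <- function(ranks_a, na, nb) {
  n <- na + nb
  u_obs <- sum(ranks_a) - na * (na + 1) / 2
  combs <- utils::combn(n, na)
  us <- colSums(matrix(seq_len(n)[combs], nrow = na)) - na * (na + 1) / 2
  mu <- na * nb / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

#' Mann-Whitney U test
#'
#' Midrank ties; exact two-sided p by enumeration when `min(nA, nB) <= 8`
#' and there are no ties, normal approximation with tie correction and
#' continuity correction otherwise.
#'
#' @param group_a,group_b numeric vectors.
#' @return list with `U` (for group A) and two-sided `p`.
#' @export
mannwhitney_test <- function(group_a, group_b) {
  stopifnot(length(group_a) > 0, length(group_b) > 0)
  na <- length(group_a); nb <- length(group_b)
  v <- c(group_a, group_b)
  rk <- rank(v)
  U <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  ties <- any(duplicated(v))
  if (!ties && min(na, nb) <= 8) {
    p <- .mw_exact_p(rk[seq_len(na)], na, nb)
  } else {
    n <- na + nb
    tie_tab <- table(v)
    tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
    sigma2 <- na * nb / 12 * (n + 1 - tie_term)
    mu <- na * nb / 2
    z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
    z <- max(z, 0)
    p <- 2 * pnorm(-z)
  }
  list(U = U, p = min(p, 1))
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' `q_(i) = min_{j >= i} p_(j) m / j`, clipped at 1, returned in input
#' order.
#'
#' @param pvalues numeric vector in [0, 1].
#' @return FDR-adjusted values.
#' @export
benjamini_hochberg <- function(pvalues) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE))
  m <- length(pvalues)
  ord <- order(pvalues)
  q <- pvalues[ord] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  out
}

#' Feature-set membership report
#'
#' For every feature (post-preliminary-filter set): Pearson tests against
#' Ki-67 LI and against cell density, a Mann-Whitney test across histology
#' (AC vs LCNEC), each batch BH-corrected separately. "Uncorrelated" /
#' "histology-independent" means FDR >= 0.05 (non-rejection). Reports the
#' three boolean sets, their intersection, and the over-representation of
#' the intersection among the top-k ranked features.
#'
#' @param table samples x features (filtered) data.frame/matrix.
#' @param ranking feature names by decreasing prognostic relevance.
#' @param ki67_li,density per-sample covariates.
#' @param histology per-sample AC/LCNEC labels.
#' @param fdr significance level on FDR (default 0.05).
#' @param top_k size of the top-ranked set inspected (default 18).
#' @return list with `per_feature` data.frame, `venn_counts` and
#'   `top_k_overrepresentation`.
#' @export
feature_set_report <- function(table, ranking, ki67_li, density, histology,
                               fdr = 0.05, top_k = 18) {
  x <- as.data.frame(table, check.names = FALSE)
  histology <- as.character(histology)
  hl <- sort(unique(histology))
  p_li <- vapply(x, function(col) pearson_test(col, ki67_li)$p, numeric(1))
  p_de <- vapply(x, function(col) pearson_test(col, density)$p, numeric(1))
  p_hi <- vapply(x, function(col)
    mannwhitney_test(col[histology == hl[1]],
                     col[histology == hl[2]])$p, numeric(1))
  q_li <- benjamini_hochberg(ifelse(is.na(p_li), 1, p_li))
  q_de <- benjamini_hochberg(ifelse(is.na(p_de), 1, p_de))
  q_hi <- benjamini_hochberg(ifelse(is.na(p_hi), 1, p_hi))
  per <- data.frame(
    feature = names(x),
    q_li = q_li, q_density = q_de, q_histology = q_hi,
    uncorrelated_li = q_li >= fdr,
    uncorrelated_density = q_de >= fdr,
    histology_independent = q_hi >= fdr,
    stringsAsFactors = FALSE)
  per$all_three <- per$uncorrelated_li & per$uncorrelated_density &
    per$histology_independent
  topf <- head(ranking, top_k)
  in_top <- per$feature %in% topf
  venn <- c(uncorrelated_li = sum(per$uncorrelated_li),
            uncorrelated_density = sum(per$uncorrelated_density),
            histology_independent = sum(per$histology_independent),
            both_uncorrelated = sum(per$uncorrelated_li &
                                      per$uncorrelated_density),
            all_three = sum(per$all_three))
  list(per_feature = per, venn_counts = venn,
       top_k_overrepresentation = list(
         frac_all_three_top = if (any(in_top)) mean(per$all_three[in_top])
         else NA_real_,
         frac_all_three_overall = mean(per$all_three)))
}
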