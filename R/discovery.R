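#' Two-sided Wilcoxon rank-sum p-value
#'
#' Thin wrapper around [stats::wilcox.test()] fixing the policy used
#' throughout discovery: the exact null distribution for small tie-free
#' samples (combined n <= 20), and the normal approximation with tie
#' correction and continuity correction otherwise. Zeros arising from
#' non-detection are ordinary (lowest, tied) values here.
#'
#' @param x,y non-empty numeric vectors
#' @return two-sided p-value
#' @export
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6)) # 0.1
wilcoxon_rank_sum <- function(x, y) {
  if (!length(x) || !length(y)) stopf("both groups must be non-empty")
  has_ties <- anyDuplicated(c(x, y)) > 0
  exact <- !has_ties && (length(x) + length(y)) <= 20
  suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided",
                exact = exact, correct = TRUE)$p.value
  )
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up FDR adjustment via [stats::p.adjust()]: q_i is the minimum over
#' ranks j >= i of m * p_(j) / j, capped at 1 and mapped back to input order.
#'
#' @param p_values numeric vector of p-values in [0, 1]
#' @return q-values in input order
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))
bh_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    stopf("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Per-stratum differential peptide discovery
#'
#' Within one baseline-eGFR stratum, compares normalized amplitudes of every
#' peptide between rapid progressors (cases) and non-rapid progressors
#' (controls) with the Wilcoxon rank-sum test (zeros entering as lowest tied
#' values, so detection-rate differences contribute), adjusts across all
#' tested peptides by Benjamini-Hochberg, and selects peptides with
#' q <= alpha that are detected in more than `min_freq` of at least one
#' group. Optionally, selection additionally requires consistent regulation:
#' the sign of the case-control median difference must be identical in
#' every cross-validation fold of the stratum.
#'
#' Housekeeping peptides are excluded from testing.
#'
#' @param matrix a normalized [peptide_matrix()]
#' @param labels labeling data.frame from [label_cohort()] (patient_id,
#'   label, stratum)
#' @param stratum stratum id 1..7 to analyse
#' @param alpha FDR level (default 0.05)
#' @param min_freq detection-frequency threshold (default 0.3, i.e.
#'   frequency over 30\% in at least one group)
#' @param require_consistent_regulation require fold-wise direction
#'   agreement (default FALSE)
#' @param cv_folds folds for the consistency check
#' @param seed seed for the consistency fold assignment
#' @return object of class `discovery_result`: a list with `stratum`,
#'   `table` (one row per peptide: p_value, q_value, fold_change,
#'   frequency_cases, frequency_controls, direction, selected),
#'   `n_cases`, `n_controls` and the parameters used
#' @export
discover_stratum <- function(matrix, labels, stratum, alpha = 0.05,
                             min_freq = 0.3,
                             require_consistent_regulation = FALSE,
                             cv_folds = 5, seed = 1) {
  in_str <- labels[labels$stratum == stratum & labels$label %in% c("rapid", "stable"), ]
  case_ids <- sort(in_str$patient_id[in_str$label == "rapid"])
  control_ids <- sort(in_str$patient_id[in_str$label == "stable"])
  if (!length(case_ids) || !length(control_ids)) {
    stopf("stratum %s lacks cases or controls", stratum)
  }
  amp <- matrix$amplitudes
  test_ids <- setdiff(colnames(amp), matrix$housekeeping_ids)
  ca <- amp[case_ids, test_ids, drop = FALSE]
  co <- amp[control_ids, test_ids, drop = FALSE]

  p <- vapply(seq_along(test_ids), function(j) {
    wilcoxon_rank_sum(ca[, j], co[, j])
  }, numeric(1))
  q <- bh_adjust(p)

  mean_pos <- function(m) apply(m, 2, function(v) if (any(v > 0)) mean(v[v > 0]) else 0)
  freq_ca <- colMeans(ca > 0)
  freq_co <- colMeans(co > 0)
  m_ca <- mean_pos(ca)
  m_co <- mean_pos(co)
  fc <- ifelse(m_co > 0, m_ca / m_co, NA_real_)
  med_diff <- apply(ca, 2, median) - apply(co, 2, median)
  direction <- ifelse(
    med_diff > 0, "up",
    ifelse(med_diff < 0, "down", ifelse(m_ca >= m_co, "up", "down"))
  )

  selected <- q <= alpha & pmax(freq_ca, freq_co) > min_freq

  consistent <- rep(TRUE, length(test_ids))
  if (require_consistent_regulation && any(selected)) {
    y <- c(rep("case", length(case_ids)), rep("control", length(control_ids)))
    folds <- stratified_folds(y, cv_folds, seed)
    f_ca <- folds[seq_along(case_ids)]
    f_co <- folds[length(case_ids) + seq_along(control_ids)]
    for (j in which(selected)) {
      signs <- vapply(seq_len(cv_folds), function(k) {
        sign(median(ca[f_ca == k, j]) - median(co[f_co == k, j]))
      }, numeric(1))
      consistent[j] <- length(unique(signs[signs != 0])) <= 1 && any(signs != 0) &&
        all(signs != 0)
    }
    selected <- selected & consistent
  }

  structure(list(
    stratum = stratum,
    table = data.frame(
      peptide_id = test_ids, p_value = p, q_value = q, fold_change = fc,
      frequency_cases = freq_ca, frequency_controls = freq_co,
      direction = direction, selected = selected,
      row.names = NULL, stringsAsFactors = FALSE
    ),
    n_cases = length(case_ids), n_controls = length(control_ids),
    params = list(alpha = alpha, min_freq = min_freq,
                  require_consistent_regulation = require_consistent_regulation,
                  cv_folds = cv_folds, seed = seed)
  ), class = "discovery_result")
}

#' @export
print.discovery_result <- function(x, ...) {
  cat(sprintf(
    "discovery_result: stratum %s, %d cases vs %d controls, %d/%d peptides selected (alpha %.3g)\n",
    x$stratum, x$n_cases, x$n_controls, sum(x$table$selected),
    nrow(x$table), x$params$alpha
  ))
  invisible(x)
}

#' Build a candidate peptide panel
#'
#' Union of a base panel (the stand-in for the published multi-peptide
#' classifier) with the peptides selected by stratum discovery:
#' de-duplicated, base panel first, then discoveries in ascending q-value
#' order (ties broken by peptide id). Provenance is tagged per peptide;
#' peptides in both sources carry "base_panel+stratum_discovery".
#'
#' @param discovery a `discovery_result` (or NULL for base panel only)
#' @param base_panel character vector of base-panel peptide ids
#' @return data.frame (peptide_id, provenance), class `peptide_panel`
#' @export
build_candidate_panel <- function(discovery, base_panel = character(0)) {
  sel <- character(0)
  if (!is.null(discovery)) {
    tab <- discovery$table[discovery$table$selected, ]
    tab <- tab[order(tab$q_value, tab$peptide_id), ]
    sel <- tab$peptide_id
  }
  ids <- c(base_panel, setdiff(sel, base_panel))
  prov <- ifelse(
    ids %in% base_panel & ids %in% sel, "base_panel+stratum_discovery",
    ifelse(ids %in% base_panel, "base_panel", "stratum_discovery")
  )
  structure(
    data.frame(peptide_id = ids, provenance = prov, stringsAsFactors = FALSE),
    class = c("peptide_panel", "data.frame")
  )
}

#' Most differential peptides of a stratum
#'
#' The k peptides with smallest q-value; ties broken by |log2 fold change|
#' descending (undefined fold changes, i.e. never detected in controls, rank
#' as maximally changed), then peptide id. Reports direction and whether
#' each peptide is in the base panel.
#'
#' @param discovery a `discovery_result`
#' @param k number of peptides (default 10; truncated to the tested count)
#' @param base_panel optional base-panel ids for the overlap flag
#' @return data.frame of the ranked top peptides
#' @export
top_differential <- function(discovery, k = 10, base_panel = character(0)) {
  tab <- discovery$table
  if (!nrow(tab)) stopf("no tested peptides")
  abs_l2fc <- abs(log2(tab$fold_change))
  abs_l2fc[!is.finite(abs_l2fc)] <- Inf
  ord <- order(tab$q_value, -abs_l2fc, tab$peptide_id)
  tab <- tab[ord, ]
  tab <- head(tab, k)
  tab$abs_log2_fc <- head(abs_l2fc[ord], k)
  tab$in_base_panel <- tab$peptide_id %in% base_panel
  rownames(tab) <- NULL
  tab
}
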