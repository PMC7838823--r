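#' Read a regulon table
#'
#' TSV with columns `regulator`, `target`, `mode` (-1/1) and `weight`
#' (in (0, 1]; defaults to 1 when absent).
#'
#' @param path TSV path.
#' @return data.frame regulator/target/mode/weight.
#' @export
read_regulon_tsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "")
  need <- c("regulator", "target", "mode")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("regulon table is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (is.null(tab$weight)) tab$weight <- 1
  tab$mode <- as.integer(tab$mode)
  tab$weight <- as.numeric(tab$weight)
  if (any(tab$weight <= 0)) stop("regulon weights must be positive")
  tab[, c("regulator", "target", "mode", "weight")]
}

#' Read a GMT gene-set file as unsigned regulons
#'
#' Each set becomes a regulator with mode +1 and weight 1 targets.
#'
#' @param path GMT path (set name, description, then member genes,
#'   tab-separated).
#' @return for [read_gmt()]: named list of character vectors;
#'   [gmt_to_regulons()] flattens it to a regulon data.frame.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    f[-(1:2)][nzchar(f[-(1:2)])]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], "")
  sets
}

#' @rdname read_gmt
#' @param sets named list as returned by [read_gmt()].
#' @export
gmt_to_regulons <- function(sets) {
  do.call(rbind, lapply(names(sets), function(nm) {
    data.frame(regulator = nm, target = sets[[nm]], mode = 1L, weight = 1,
               stringsAsFactors = FALSE)
  }))
}

#' Read a differential-statistics table
#'
#' TSV with columns `feature_id`, `statistic` (moderated-t-like signed
#' statistic), `p_value` and optionally `log_fc`.
#'
#' @param path TSV path.
#' @export
read_stat_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "")
  need <- c("feature_id", "statistic", "p_value")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("statistics table is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  if (is.null(tab$log_fc)) tab$log_fc <- tab$statistic
  tab
}

#' Footprint activity estimation (normalized enrichment scores)
#'
#' Estimates regulator activities from the differential statistics of
#' their targets. Statistics of all measured features are converted to
#' standard-normal scores via their fractional ranks (average ranks for
#' ties): z_i = qnorm((rank_i - 0.5) / n). A regulator's enrichment score
#' is the weighted, mode-signed sum of its measured targets' z-scores,
#' standardized by the exact analytic null of a random permutation of the
#' statistics (mean zero; variance from the finite z-score population
#' sampled without replacement). The resulting NES is therefore expressed
#' in standard deviations of the permutation null.
#'
#' Regulators with fewer than `min_targets` measured targets are omitted;
#' regulators with no measured targets are dropped with a warning.
#'
#' @param regulons data.frame regulator/target/mode/weight.
#' @param stats data.frame feature_id/statistic (a StatTable).
#' @param min_targets minimum number of measured targets (reference
#'   defaults: 25 for TF regulons, 5 for kinase/phosphatase regulons).
#' @return data.frame `node`, `nes`, `n_targets` (class `activity_table`).
#' @export
estimate_activities <- function(regulons, stats, min_targets = 5) {
  stopifnot(min_targets >= 1)
  if (!nrow(stats)) stop("statistics table is empty")
  stat <- stats$statistic
  if (any(!is.finite(stat))) stop("statistics must be finite")
  n <- length(stat)
  z <- stats::qnorm((rank(stat, ties.method = "average") - 0.5) / n)
  names(z) <- stats$feature_id
  sigma2 <- mean(z^2) # population variance of the z grid (mean is 0)
  reg_split <- split(regulons[, c("target", "mode", "weight")],
                     regulons$regulator)
  res <- lapply(names(reg_split), function(r) {
    tab <- reg_split[[r]]
    tab <- tab[!duplicated(tab$target), , drop = FALSE]
    tab <- tab[tab$target %in% names(z), , drop = FALSE]
    k <- nrow(tab)
    if (k == 0L) return(NULL)
    if (k < min_targets) return(NA)
    a <- tab$weight * tab$mode
    # permutation-null variance of sum(a * z_perm), sampling w/o replacement
    v <- sigma2 * (sum(a^2) - (sum(a)^2 - sum(a^2)) / (n - 1))
    v <- max(v, .Machine$double.eps)
    data.frame(node = r, nes = sum(a * z[tab$target]) / sqrt(v),
               n_targets = k, stringsAsFactors = FALSE)
  })
  empty <- names(reg_split)[vapply(res, is.null, TRUE)]
  if (length(empty)) {
    warning("regulon(s) with no measured targets omitted: ",
            paste(empty, collapse = ", "))
  }
  res <- res[!vapply(res, function(x) is.null(x) || !is.data.frame(x), TRUE)]
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(node = character(), nes = numeric(), n_targets = integer(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("activity_table", "data.frame")
  out
}

#' Per-sample footprint activities
#'
#' Each feature row of the data matrix is scaled across samples (minus
#' mean over standard deviation); zero-variance rows are dropped. The
#' scaled values of each sample column are then used as the feature
#' statistics for [estimate_activities()], yielding a regulator x sample
#' NES matrix relative to the across-sample distribution.
#'
#' @param data numeric matrix, features x samples (>= 3 samples).
#' @param regulons data.frame regulator/target/mode/weight.
#' @param min_targets minimum measured targets per regulator.
#' @return numeric matrix regulators x samples.
#' @export
per_sample_activities <- function(data, regulons, min_targets = 5) {
  data <- as.matrix(data)
  if (ncol(data) < 3L) stop("per-sample activities need at least 3 samples")
  sds <- apply(data, 1L, stats::sd)
  keep <- is.finite(sds) & sds > 0
  data <- data[keep, , drop = FALSE]
  if (!nrow(data)) stop("no feature with nonzero variance")
  scaled <- t(scale(t(data)))
  cols <- lapply(seq_len(ncol(scaled)), function(j) {
    suppressWarnings(estimate_activities(
      regulons,
      data.frame(feature_id = rownames(scaled), statistic = scaled[, j],
                 stringsAsFactors = FALSE),
      min_targets = min_targets))
  })
  regs <- sort(unique(unlist(lapply(cols, function(a) a$node))))
  out <- matrix(NA_real_, length(regs), ncol(scaled),
                dimnames = list(regs, colnames(data)))
  for (j in seq_along(cols)) {
    out[cols[[j]]$node, j] <- cols[[j]]$nes
  }
  out
}

#' Select deregulated inputs and measurements
#'
#' Regulators whose |NES| exceeds `nes_cut` (strictly) are considered
#' deregulated and kept with their NES as value; metabolites with an
#' uncorrected p-value below `p_cut` (strictly) are kept with the sign of
#' their statistic.
#'
#' @param activities an activity table (`node`, `nes`).
#' @param metab_stats StatTable for metabolites (`feature_id`,
#'   `statistic`, `p_value`).
#' @param nes_cut absolute NES cutoff (default 1.7).
#' @param p_cut p-value cutoff (default 0.05).
#' @return list with data.frames `signaling` (node, value = NES) and
#'   `metabolites` (node, value = sign of statistic).
#' @export
select_inputs <- function(activities, metab_stats, nes_cut = 1.7,
                          p_cut = 0.05) {
  stopifnot(nes_cut > 0)
  sig <- activities[abs(activities$nes) > nes_cut, , drop = FALSE]
  signaling <- data.frame(node = sig$node, value = sig$nes,
                          stringsAsFactors = FALSE)
  met <- metab_stats[metab_stats$p_value < p_cut, , drop = FALSE]
  metabolites <- data.frame(node = as.character(met$feature_id),
                            value = sign(met$statistic),
                            stringsAsFactors = FALSE)
  if (!nrow(signaling) && !nrow(metabolites)) {
    warning("no deregulated node passes the selection thresholds")
  }
  list(signaling = signaling, metabolites = metabolites)
}
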