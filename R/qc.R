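# Sample and marker quality control for genotype panels.
#
# The filters mirror routine SNP-chip QC: sample call rate, sample
# heterozygosity outliers, per-marker missingness, minor allele
# frequency, fixed markers, and redundancy between adjacent markers.
# MDS coordinates are exposed for visual outlier inspection; removal of
# MDS outliers is deliberately left to the user.

removal_df <- function(ids, type, reason, value) {
  n <- length(ids)
  data.frame(id = ids, type = rep_len(type, n),
             reason = rep_len(reason, n), value = rep_len(value, n),
             stringsAsFactors = FALSE, row.names = NULL)
}

new_qc_report <- function(removed = NULL,
                          thresholds = list()) {
  removed <- removed %||% data.frame(id = character(), type = character(),
                                     reason = character(), value = double(),
                                     stringsAsFactors = FALSE)
  structure(list(removed = removed, thresholds = thresholds),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("qc_report:", nrow(x$removed), "removal(s)\n")
  if (nrow(x$removed))
    print(table(type = x$removed$type, reason = x$removed$reason))
  invisible(x)
}

#' Write a QC report as TSV
#'
#' Columns: `id`, `type` (sample|marker), `reason`, `value` (the
#' offending statistic).
#'
#' @param report a `qc_report` as returned by the filter functions.
#' @param path output path.
#' @export
write_qc_report <- function(report, path) {
  utils::write.table(report$removed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(report)
}

#' Filter samples by call rate and heterozygosity
#'
#' Two passes in fixed order: first samples with call rate (fraction of
#' non-missing dosages) below `call_rate_min` are removed; then samples
#' whose heterozygosity (fraction of non-missing dosages equal to 1)
#' deviates from the remaining samples' mean by more than `het_sd_max`
#' standard deviations.  The heterozygosity rule is two-sided, the
#' conservative PLINK-style reading.  If the heterozygosity SD is zero
#' (all samples identical) no heterozygosity removals occur.
#'
#' @param panel a [genotype_panel] with n >= 2.
#' @param call_rate_min minimum call rate, default 0.98.
#' @param het_sd_max maximum |het - mean| in SD units, default 3.
#' @return list with elements `panel` (filtered) and `report`
#'   (`qc_report`).
#' @export
filter_samples <- function(panel, call_rate_min = 0.98, het_sd_max = 3.0) {
  stopifnot(inherits(panel, "genotype_panel"))
  d <- panel$dosages
  if (nrow(d) < 2L) stop_("sample filtering needs n >= 2")
  called <- !is.na(d)
  call_rate <- rowMeans(called)
  rm_cr <- call_rate < call_rate_min
  removed <- removal_df(rownames(d)[rm_cr], "sample", "call_rate",
                        call_rate[rm_cr])
  keep <- !rm_cr
  if (!any(keep)) stop_("all samples removed by call-rate filter")
  het <- rowSums(d[keep, , drop = FALSE] == 1L, na.rm = TRUE) /
    rowSums(called[keep, , drop = FALSE])
  mu <- mean(het); sdev <- stats::sd(het)
  rm_het <- if (is.na(sdev) || sdev == 0) rep(FALSE, sum(keep)) else
    abs(het - mu) > het_sd_max * sdev
  if (any(rm_het))
    removed <- rbind(removed,
                     removal_df(rownames(d)[keep][rm_het], "sample",
                                "heterozygosity", het[rm_het]))
  keep_ids <- setdiff(rownames(d), removed$id)
  if (!length(keep_ids)) stop_("all samples removed by QC")
  out <- panel[match(keep_ids, rownames(d)), ]
  list(panel = out,
       report = new_qc_report(removed,
                              list(call_rate_min = call_rate_min,
                                   het_sd_max = het_sd_max)))
}

marker_maf <- function(col) {
  called <- !is.na(col)
  af <- sum(col[called]) / (2 * sum(called))
  min(af, 1 - af)
}

#' Filter markers by missingness, MAF and fixation
#'
#' Removes markers with any missing genotype, markers whose minor allele
#' frequency (computed from non-missing calls as dosage-sum over twice
#' the called count) is below `maf_min`, and fixed markers (a single
#' genotype class present in all samples).  Each removed marker carries
#' one primary reason, with priority missing > fixed > maf (a fixed
#' homozygous column also fails the MAF test; it is reported as fixed).
#' Optionally finishes with the adjacent-redundancy pass
#' ([drop_adjacent_redundant()]).
#'
#' @param panel a [genotype_panel].
#' @param maf_min minimum minor allele frequency, default 0.03.
#' @param drop_redundant also drop adjacent redundant markers
#'   (default TRUE, matching the full marker-QC recipe).
#' @return list with elements `panel` and `report`.
#' @export
filter_markers <- function(panel, maf_min = 0.03, drop_redundant = TRUE) {
  stopifnot(inherits(panel, "genotype_panel"))
  d <- panel$dosages
  n_missing <- colSums(is.na(d))
  maf <- apply(d, 2L, marker_maf)
  n_classes <- apply(d, 2L, function(col) length(unique(col[!is.na(col)])))
  reason <- rep(NA_character_, ncol(d))
  value <- rep(NA_real_, ncol(d))
  fixed <- n_classes <= 1L
  low_maf <- !is.na(maf) & maf < maf_min
  reason[low_maf] <- "maf";      value[low_maf] <- maf[low_maf]
  reason[fixed]   <- "fixed";    value[fixed]   <- n_classes[fixed]
  reason[n_missing > 0L] <- "missing"
  value[n_missing > 0L] <- n_missing[n_missing > 0L]
  rm_idx <- which(!is.na(reason))
  removed <- removal_df(colnames(d)[rm_idx], "marker", reason[rm_idx],
                        value[rm_idx])
  if (length(rm_idx) == ncol(d)) stop_("all markers removed by QC")
  out <- if (length(rm_idx)) panel[, -rm_idx] else panel
  report <- new_qc_report(removed, list(maf_min = maf_min))
  if (drop_redundant) {
    red <- drop_adjacent_redundant(out)
    out <- red$panel
    report$removed <- rbind(report$removed, red$report$removed)
  }
  list(panel = out, report = report)
}

#' Drop adjacent redundant markers
#'
#' Scanning each chromosome left to right (map order), a marker whose
#' dosage column is identical to the retained marker immediately
#' preceding it is dropped.  Comparison is exact dosage equality
#' (identical genotypic profiles); chromosomes are never compared
#' across, and a run of k identical adjacent columns keeps only the
#' first.
#'
#' @param panel a [genotype_panel].
#' @return list with elements `panel` and `report`.
#' @export
drop_adjacent_redundant <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  d <- panel$dosages
  map <- panel$map
  drop <- logical(ncol(d))
  for (chr in unique(map$chromosome)) {
    idx <- which(map$chromosome == chr)
    if (length(idx) < 2L) next
    last_kept <- idx[1L]
    for (j in idx[-1L]) {
      same <- identical(unname(d[, j]), unname(d[, last_kept]))
      if (same) drop[j] <- TRUE else last_kept <- j
    }
  }
  removed <- removal_df(colnames(d)[drop], "marker",
                        "redundant_adjacent", NA_real_)
  if (all(drop)) stop_("all markers removed as redundant")
  out <- if (any(drop)) panel[, !drop] else panel
  list(panel = out, report = new_qc_report(removed))
}

#' Classical MDS coordinates from allele sharing
#'
#' Computes the pairwise identity-by-state distance `1 - IBS` between
#' samples, where the IBS proportion for a sample pair is
#' `mean(1 - |x_i - x_j| / 2)` over markers, and embeds it with
#' classical multidimensional scaling (principal coordinates,
#' [stats::cmdscale()]).  Coordinates are returned for visual outlier
#' inspection only; no samples are removed.
#'
#' @param panel a [genotype_panel] with no missing dosages (run the
#'   filters first), unless `impute_mean = TRUE`.
#' @param k number of dimensions, must be < n.  Default 2.
#' @param impute_mean replace missing dosages by the marker mean before
#'   computing distances.
#' @return n x k matrix of coordinates, rows named by sample.
#' @seealso [centroid_distance()] for a numeric outlier screen.
#' @export
mds_coordinates <- function(panel, k = 2, impute_mean = FALSE) {
  stopifnot(inherits(panel, "genotype_panel"))
  d <- panel$dosages
  n <- nrow(d)
  if (k >= n) stop_("k must be < number of samples (k=", k, ", n=", n, ")")
  if (anyNA(d)) {
    if (!impute_mean)
      stop_("panel has missing dosages; filter first or set impute_mean")
    mns <- colMeans(d, na.rm = TRUE)
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- mns[idx[, 2L]]
  }
  dist_ibs <- as.matrix(stats::dist(d, method = "manhattan")) /
    (2 * ncol(d))
  coords <- stats::cmdscale(dist_ibs, k = k)
  # cmdscale drops columns when the distance matrix is rank deficient
  # (e.g. duplicated samples); pad with zeros to honour the k contract.
  if (ncol(coords) < k)
    coords <- cbind(coords, matrix(0, n, k - ncol(coords)))
  rownames(coords) <- rownames(panel$dosages)
  coords
}

#' Distance of each sample from the MDS centroid
#'
#' Convenience helper for screening MDS outliers numerically: Euclidean
#' distance of each sample's coordinates from the centroid.
#'
#' @param coords matrix as returned by [mds_coordinates()].
#' @return named numeric vector.
#' @export
centroid_distance <- function(coords) {
  ctr <- colMeans(coords)
  stats::setNames(sqrt(rowSums(sweep(coords, 2L, ctr)^2)),
                  rownames(coords))
}
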