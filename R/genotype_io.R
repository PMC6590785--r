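# Panel I/O: tab-separated dosage + map tables (the canonical dialect,
# shaped like PLINK --recode A output) and read-only VCF ingress.

#' Read a genotype panel from dosage and map tables
#'
#' The dosage file is a delimited table with samples in rows: first
#' column sample ID, remaining columns 0/1/2 dosages (missing entries as
#' `missing`).  The map file has columns `marker_id`, `chromosome`,
#' `position`.  Map row order must match dosage column order.
#'
#' @param dosage_path,map_path file paths.
#' @param sep field separator, default tab.
#' @param missing token representing a missing dosage, default `"NA"`.
#' @return a [genotype_panel].
#' @seealso [write_panel()] for the inverse; round-trips are exact.
#' @export
read_panel <- function(dosage_path, map_path, sep = "\t", missing = "NA") {
  dos <- utils::read.table(dosage_path, header = TRUE, sep = sep,
                           colClasses = "character",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(dos) < 2L) stop_("dosage file needs an ID column plus markers")
  samples <- dos[[1L]]
  cells <- as.matrix(dos[, -1L, drop = FALSE])
  cells[cells == missing] <- NA_character_
  ok <- is.na(cells) | cells %in% c("0", "1", "2")
  if (!all(ok))
    stop_("invalid dosage token(s) in ", dosage_path, ": ",
          paste(utils::head(unique(cells[!ok]), 5), collapse = ", "))
  storage.mode(cells) <- "integer"
  map <- utils::read.table(map_path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(map) < 3L)
    stop_("map file needs >= 3 columns (marker_id, chromosome, position)")
  names(map)[1:3] <- c("marker_id", "chromosome", "position")
  if (nrow(map) != ncol(cells))
    stop_("dimension mismatch: ", ncol(cells), " dosage columns vs ",
          nrow(map), " map rows")
  genotype_panel(cells, map, samples = samples)
}

#' Write a genotype panel to dosage and map tables
#'
#' Inverse of [read_panel()]: `read_panel()` on the written files
#' reproduces the panel exactly (bit-exact dosages, marker and sample
#' order preserved).
#'
#' @param panel a [genotype_panel].
#' @param dosage_path,map_path output file paths.
#' @param sep field separator, default tab.
#' @param missing token written for missing dosages.
#' @return invisibly, the panel.
#' @export
write_panel <- function(panel, dosage_path, map_path, sep = "\t",
                        missing = "NA") {
  stopifnot(inherits(panel, "genotype_panel"))
  d <- panel$dosages
  out <- data.frame(sample_id = rownames(d), d, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, dosage_path, sep = sep, quote = FALSE,
                     row.names = FALSE, na = missing)
  utils::write.table(panel$map, map_path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(panel)
}

#' Read a VCF as a genotype panel
#'
#' Diploid biallelic GT fields are converted to ALT-allele dosages:
#' `0/0` -> 0, `0/1` or `1/0` -> 1, `1/1` -> 2, `./.` -> missing; phased
#' separators (`|`) are accepted.  Multi-allelic sites are skipped with a
#' warning.  Which allele is counted is arbitrary but fixed (it only
#' flips the sign of estimated effects).
#'
#' @param vcf_path path to a VCF 4.x file (uncompressed or gzipped).
#' @return a [genotype_panel]; positions are the VCF 1-based POS.
#' @export
read_vcf_panel <- function(vcf_path) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  biallelic <- !is.na(alt) & !grepl(",", alt, fixed = TRUE)
  if (any(!biallelic))
    warning(sum(!biallelic), " multi-allelic site(s) skipped",
            call. = FALSE)
  if (!any(biallelic)) stop_("no biallelic sites in ", vcf_path)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[biallelic, , drop = FALSE]
  fix <- fix[biallelic, , drop = FALSE]
  core <- substr(gsub("|", "/", gt, fixed = TRUE), 1, 3)
  dos <- matrix(NA_integer_, nrow = nrow(core), ncol = ncol(core))
  dos[core == "0/0"] <- 0L
  dos[core %in% c("0/1", "1/0")] <- 1L
  dos[core == "1/1"] <- 2L
  ids <- fix[, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix[noid, "CHROM"], "_", fix[noid, "POS"])
  map <- data.frame(marker_id = ids, chromosome = fix[, "CHROM"],
                    position = as.integer(fix[, "POS"]),
                    stringsAsFactors = FALSE)
  genotype_panel(t(dos), map, samples = colnames(gt))
}

#' Read / write a phenotype table
#'
#' Tab-separated with header; first column sample ID, second the trait
#' value (assumed pre-corrected for fixed effects).  Additional columns
#' (e.g. true breeding values from a simulation) are preserved.
#'
#' @param path file path.
#' @return data frame with at least columns `sample_id`, `value`.
#' @export
read_phenotypes <- function(path) {
  ph <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(ph) < 2L) stop_("phenotype file needs >= 2 columns")
  names(ph)[1:2] <- c("sample_id", "value")
  ph$sample_id <- as.character(ph$sample_id)
  if (anyDuplicated(ph$sample_id))
    stop_("duplicate sample IDs in phenotype file")
  ph
}

#' @rdname read_phenotypes
#' @param pheno data frame as returned by [read_phenotypes()].
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.table(pheno, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(pheno)
}

#' Align a phenotype table to a panel
#'
#' @param panel a [genotype_panel].
#' @param pheno data frame with `sample_id` and `value` columns.
#' @return numeric vector of phenotypes in panel sample order.
#' @export
align_phenotypes <- function(panel, pheno) {
  idx <- match(rownames(panel$dosages), pheno$sample_id)
  if (anyNA(idx))
    stop_("phenotypes missing for sample(s): ",
          paste(utils::head(rownames(panel$dosages)[is.na(idx)], 5),
                collapse = ", "))
  stats::setNames(pheno$value[idx], pheno$sample_id[idx])
}
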