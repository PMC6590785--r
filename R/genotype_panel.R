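#' Construct a genotype panel
#'
#' A genotype panel bundles an `n x p` SNP dosage matrix (allele counts
#' 0/1/2, `NA` for missing) with its marker map.  It is the canonical
#' container consumed by the quality-control, simulation, screening and
#' prediction functions.
#'
#' @param dosages numeric or integer matrix, samples in rows, markers in
#'   columns; every non-missing entry must be 0, 1 or 2.
#' @param map data frame with columns `marker_id`, `chromosome`,
#'   `position` (1-based base pairs), one row per dosage column, in
#'   column order.
#' @param samples character vector of sample identifiers; defaults to the
#'   dosage row names.
#'
#' @details Marker identifiers must be unique and, within each
#' chromosome, map rows must be sorted by ascending position (the
#' adjacency-based redundancy filter and chromosome-conditioned grouping
#' rely on this).  Row order of the map is the column order of the
#' dosage matrix; no function in the package ever silently reorders
#' markers or samples.
#'
#' @return An object of class `genotype_panel`: a list with elements
#'   `dosages` (matrix with sample row names and marker column names) and
#'   `map` (data frame).
#' @examples
#' map <- data.frame(marker_id = c("m1", "m2"), chromosome = 1,
#'                   position = c(100L, 200L))
#' geno <- matrix(c(0, 1, 2, 1), 2, 2,
#'                dimnames = list(c("s1", "s2"), map$marker_id))
#' genotype_panel(geno, map)
#' @export
genotype_panel <- function(dosages, map, samples = rownames(dosages)) {
  if (!is.matrix(dosages)) dosages <- as.matrix(dosages)
  n <- nrow(dosages); p <- ncol(dosages)
  if (n < 1L || p < 1L)
    stop_("a genotype panel needs at least 1 sample and 1 marker (n=",
          n, ", p=", p, ")")
  if (is.null(samples)) samples <- paste0("sample", seq_len(n))
  samples <- as.character(samples)
  if (length(samples) != n)
    stop_("length(samples) != nrow(dosages)")
  if (anyDuplicated(samples))
    stop_("duplicate sample IDs: ",
          paste(unique(samples[duplicated(samples)]), collapse = ", "))
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  need <- c("marker_id", "chromosome", "position")
  if (!all(need %in% names(map)))
    stop_("map must have columns ", paste(need, collapse = ", "))
  map <- map[need]
  map$marker_id <- as.character(map$marker_id)
  map$position <- as.integer(map$position)
  if (nrow(map) != p)
    stop_("map has ", nrow(map), " rows but dosage matrix has ", p,
          " columns")
  if (anyDuplicated(map$marker_id))
    stop_("duplicate marker IDs: ",
          paste(unique(map$marker_id[duplicated(map$marker_id)]),
                collapse = ", "))
  if (any(map$position < 0L, na.rm = TRUE))
    stop_("map positions must be >= 0")
  for (chr in unique(map$chromosome)) {
    pos <- map$position[map$chromosome == chr]
    if (is.unsorted(pos))
      stop_("map not sorted by position within chromosome ", chr)
  }
  bad <- !(dosages %in% c(0, 1, 2)) & !is.na(dosages)
  if (any(bad))
    stop_("invalid dosage values (must be 0/1/2 or missing): found ",
          paste(utils::head(unique(dosages[bad]), 5), collapse = ", "))
  dimnames(dosages) <- list(samples, map$marker_id)
  rownames(map) <- NULL
  structure(list(dosages = dosages, map = map), class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  d <- dim(x$dosages)
  nchr <- length(unique(x$map$chromosome))
  nmiss <- sum(is.na(x$dosages))
  cat("genotype_panel: ", d[1], " samples x ", d[2], " markers on ",
      nchr, " chromosome", if (nchr != 1) "s", "\n", sep = "")
  cat("  missing dosages: ", nmiss,
      sprintf(" (%.2f%%)", 100 * nmiss / prod(d)), "\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$dosages)

#' Number of samples / markers in a panel
#' @param panel a [genotype_panel].
#' @return integer count.
#' @export
n_samples <- function(panel) nrow(panel$dosages)

#' @rdname n_samples
#' @export
n_markers <- function(panel) ncol(panel$dosages)

#' Subset a genotype panel
#'
#' @param x a [genotype_panel].
#' @param i sample index (logical, integer or sample IDs).
#' @param j marker index (logical, integer or marker IDs).
#' @param ... ignored.
#' @return a [genotype_panel] with the selected samples and markers, map
#'   rows kept in the original order.
#' @export
`[.genotype_panel` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$dosages))
  if (missing(j)) j <- seq_len(ncol(x$dosages))
  if (is.character(j)) j <- match(j, x$map$marker_id)
  if (anyNA(j)) stop_("unknown marker ID in panel subset")
  d <- x$dosages[i, j, drop = FALSE]
  genotype_panel(d, x$map[j, , drop = FALSE], samples = rownames(d))
}
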