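# Spatiotemporal expression matrix assembly and expression-derived gene
# sets. The matrix follows the developmental-transcriptome convention:
# replicate RPKM values measured in the same (region, stage) coordinate are
# averaged, a zero mean is treated as unobserved (n/a), and observed means
# are log10-transformed.

#' Default developmental stage vocabulary
#'
#' The ordered stage labels used when none are supplied. Labels ending in
#' `pcw` (post-conception weeks) are prenatal; everything else is postnatal.
#'
#' @return Character vector of ordered stage labels.
#' @export
brainspan_stages <- function() {
  c("8pcw", "9pcw", "12pcw", "13pcw", "16pcw", "17pcw", "21pcw", "24pcw",
    "25pcw", "26pcw", "35pcw", "37pcw",
    "4mos", "10mos", "1yr", "2yrs", "3yrs", "4yrs", "8yrs", "11yrs",
    "13yrs", "15yrs", "18yrs", "19yrs", "21yrs", "23yrs", "30yrs",
    "36yrs", "37yrs", "40yrs")
}

stage_period <- function(stages) {
  ifelse(grepl("pcw$", stages), "prenatal", "postnatal")
}

#' Assemble the genes x spatiotemporal-coordinates expression matrix
#'
#' Per (gene, region, stage) coordinate, replicate RPKM values are averaged
#' arithmetically (zeros participate in the average); a cell is missing iff
#' the mean is 0, and otherwise holds `log10(mean)`. Genes with no observed
#' cell are dropped and counted.
#'
#' @param records Long-format expression tibble (`gene`, `region`, `stage`,
#'   `rpkm`), replicates as repeated rows.
#' @param gene_filter Optional character vector restricting the rows.
#' @param stage_levels Ordered stage vocabulary; coordinates are ordered by
#'   region then stage position in this vector. Stages not in the
#'   vocabulary are an error (ordering is configured, never inferred
#'   lexically).
#' @param zero_policy `"average"` (default: zeros enter the replicate mean)
#'   or `"drop"` (zero replicates are removed before averaging).
#'
#' @return An `expr_matrix`: a numeric matrix (genes x coordinates, columns
#'   named `region|stage`) with attributes `coords` (tibble `region`,
#'   `stage`, `period`) and `dropped_genes`.
#' @export
assemble_matrix <- function(records, gene_filter = NULL,
                            stage_levels = brainspan_stages(),
                            zero_policy = c("average", "drop")) {
  zero_policy <- match.arg(zero_policy)
  stopifnot(nrow(records) > 0)
  if (any(records$rpkm < 0)) abort("negative RPKM", class = "dgnet_validation_error")
  if (!is.null(gene_filter)) {
    records <- filter(records, .data$gene %in% gene_filter)
    if (nrow(records) == 0) abort("no records left after gene_filter")
  }
  unknown <- setdiff(unique(records$stage), stage_levels)
  if (length(unknown) > 0) {
    abort(sprintf("stage label(s) not in the configured vocabulary: %s",
                  paste(unknown, collapse = ", ")))
  }
  if (zero_policy == "drop") records <- filter(records, .data$rpkm > 0)

  agg <- summarise(group_by(records, .data$gene, .data$region, .data$stage),
                   mean_rpkm = mean(.data$rpkm), .groups = "drop")
  agg$value <- ifelse(agg$mean_rpkm > 0, log10(agg$mean_rpkm), NA_real_)

  regions <- sort(unique(agg$region))
  stages <- stage_levels[stage_levels %in% unique(agg$stage)]
  coords <- tidyr::expand_grid(region = regions, stage = stages)
  coords$period <- stage_period(coords$stage)
  coord_key <- paste(coords$region, coords$stage, sep = "|")

  genes <- sort(unique(agg$gene))
  m <- matrix(NA_real_, nrow = length(genes), ncol = length(coord_key),
              dimnames = list(genes, coord_key))
  idx <- cbind(match(agg$gene, genes),
               match(paste(agg$region, agg$stage, sep = "|"), coord_key))
  m[idx] <- agg$value

  observed <- rowSums(!is.na(m)) > 0
  dropped <- rownames(m)[!observed]
  if (length(dropped) > 0) {
    inform(sprintf("assemble_matrix: dropped %d gene(s) with no observed cell",
                   length(dropped)))
  }
  if (!is.null(gene_filter)) {
    absent <- setdiff(gene_filter, genes)
    if (length(absent) > 0) {
      inform(sprintf("assemble_matrix: %d gene(s) in gene_filter had no expression records",
                     length(absent)))
    }
  }
  m <- m[observed, , drop = FALSE]
  structure(m, coords = coords, dropped_genes = dropped,
            class = c("expr_matrix", class(m)))
}

#' Coordinate table of an expression matrix
#' @param x An `expr_matrix`.
#' @return Tibble with `region`, `stage`, `period`, one row per column.
#' @export
expr_coords <- function(x) attr(x, "coords")

#' @method as_tibble expr_matrix
#' @export
as_tibble.expr_matrix <- function(x, ...) {
  co <- expr_coords(x)
  out <- tidyr::expand_grid(gene = rownames(x), coord = colnames(x))
  out$value <- as.vector(t(unclass(x)))
  left_join(out, mutate(co, coord = paste(.data$region, .data$stage, sep = "|")),
            by = "coord")
}

#' Filter an expression matrix to brain-expressed genes
#'
#' Keeps rows whose gene is expressed above `threshold` (strictly) in an
#' auxiliary brain-expression reference (e.g. nTPM values). Genes absent
#' from the reference are treated as not expressed and counted.
#'
#' @param matrix An `expr_matrix` (or any matrix with gene rownames).
#' @param reference Tibble with columns `gene` and `ntpm`.
#' @param threshold Strict lower bound on `ntpm` (default 1).
#' @return The row-filtered matrix (attributes preserved).
#' @export
filter_brain_expressed <- function(matrix, reference, threshold = 1) {
  stopifnot(threshold >= -Inf, all(c("gene", "ntpm") %in% names(reference)))
  ntpm <- setNames(reference$ntpm, reference$gene)
  genes <- rownames(matrix)
  absent <- genes[!genes %in% names(ntpm)]
  if (length(absent) > 0) {
    inform(sprintf("filter_brain_expressed: %d gene(s) absent from the reference treated as not expressed",
                   length(absent)))
  }
  keep <- genes %in% names(ntpm) & !is.na(ntpm[genes]) & ntpm[genes] > threshold
  out <- matrix[keep, , drop = FALSE]
  structure(out, coords = attr(matrix, "coords"),
            dropped_genes = attr(matrix, "dropped_genes"),
            class = class(matrix))
}

#' Build per-region gene sets from an expression matrix
#'
#' One gene set per region: the genes whose value strictly exceeds
#' `threshold` in at least one coordinate of that region (e.g. logRPKM > 2
#' for a log-scale matrix, or TPM > 9 for a linear one). Regions with no
#' qualifying gene are omitted with a warning.
#'
#' @param matrix An `expr_matrix`.
#' @param threshold Strict expression threshold (default 2, log10 scale).
#' @param name Collection name.
#' @return A [gene_set_collection()] with one set per qualifying region.
#' @export
build_region_gene_sets <- function(matrix, threshold = 2,
                                   name = "region_expression") {
  co <- expr_coords(matrix)
  if (is.null(co)) abort("matrix has no coordinate attribute; use assemble_matrix()")
  sets <- lapply(unique(co$region), function(r) {
    cols <- which(co$region == r)
    hit <- rowSums(unclass(matrix)[, cols, drop = FALSE] > threshold,
                   na.rm = TRUE) > 0
    rownames(matrix)[hit]
  })
  names(sets) <- unique(co$region)
  empty <- lengths(sets) == 0
  if (any(empty)) {
    warn(sprintf("build_region_gene_sets: region(s) with no qualifying genes omitted: %s",
                 paste(names(sets)[empty], collapse = ", ")))
    sets <- sets[!empty]
  }
  gene_set_collection(sets, name = name)
}
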