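# Readers and writers for the external formats the pipeline consumes:
# tab-delimited PPI edge tables, GMT gene-set collections, long-format
# expression tables, and TSV result tables. No science logic lives here.

# Match a column by a set of case-insensitive regular expressions; returns
# the first matching column name or NA.
match_column <- function(cols, patterns) {
  for (p in patterns) {
    hit <- grep(p, cols, ignore.case = TRUE, value = TRUE)
    if (length(hit) > 0) return(hit[[1]])
  }
  NA_character_
}

#' Read a tab-delimited protein-protein interaction table
#'
#' Reads a BioGRID-TAB-like edge table (two interactor symbol columns, a
#' PSI-MI interaction-type code, an optional source-database column and an
#' optional confidence score), filters by interaction type and confidence,
#' removes self-loops and collapses duplicate undirected pairs.
#'
#' Interaction-type filtering defaults to direct interactions (`MI:0407`)
#' and physical associations (`MI:0915`). The confidence filter is
#' inclusive (`>= min_confidence`), so a threshold of 0.63 keeps
#' medium-confidence edges scored exactly 0.63.
#'
#' @param path Path to a tab-delimited file with a header row. Columns are
#'   located by name: interactor columns matching e.g. `interactor_a`/
#'   `gene_a`/`symbol_a`, an MI-code column matching `mi`/`interaction_type`,
#'   optionally `source`/`db` and `confidence`/`score`.
#' @param mi_filter Character vector of PSI-MI codes to retain, or `NULL` to
#'   retain every interaction type (including unknown codes).
#' @param min_confidence Minimum confidence score (inclusive), or `NULL` for
#'   no confidence filtering. Edges with a missing score are dropped when a
#'   threshold is set.
#'
#' @return A tibble of undirected edges with columns `gene_a`, `gene_b`
#'   (canonically ordered so `gene_a < gene_b`), `mi_code`, `source_db`,
#'   `confidence`. One row per undirected pair.
#' @export
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("interactor_a\tinteractor_b\tmi_code\tsource_db\tscore",
#'              "TP53\tMDM2\tMI:0407\tdb1\t0.9",
#'              "MDM2\tTP53\tMI:0915\tdb1\t0.8"), f)
#' read_ppi_table(f)
read_ppi_table <- function(path, mi_filter = c("MI:0407", "MI:0915"),
                           min_confidence = NULL) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, show_col_types = FALSE)
  cols <- names(raw)
  col_a <- match_column(cols, c("^(interactor|gene|symbol|protein)[._ ]?a$",
                                "interactor.*a", "symbol.*a"))
  col_b <- match_column(cols, c("^(interactor|gene|symbol|protein)[._ ]?b$",
                                "interactor.*b", "symbol.*b"))
  col_mi <- match_column(cols, c("^mi([._ ]?code)?$", "interaction[._ ]?type", "\\bmi\\b"))
  col_src <- match_column(cols, c("^source([._ ]?db)?$", "database"))
  col_sc <- match_column(cols, c("^(confidence|score)$", "confidence", "score"))

  mandatory <- c("interactor A" = col_a, "interactor B" = col_b, "MI code" = col_mi)
  if (anyNA(mandatory)) {
    abort(sprintf("PPI table %s is missing mandatory column(s): %s",
                  path, paste(names(mandatory)[is.na(mandatory)], collapse = ", ")),
          class = "dgnet_format_error")
  }

  conf <- rep(NA_real_, nrow(raw))
  if (!is.na(col_sc)) {
    sc_chr <- raw[[col_sc]]
    conf <- suppressWarnings(as.numeric(sc_chr))
    bad <- which(!is.na(sc_chr) & sc_chr != "" & sc_chr != "-" & is.na(conf))
    if (length(bad) > 0) {
      abort(sprintf("Unparsable confidence score '%s' on line %d of %s",
                    sc_chr[bad[1]], bad[1] + 1L, path),
            class = "dgnet_format_error")
    }
  }

  edges <- tibble(
    gene_a = as.character(raw[[col_a]]),
    gene_b = as.character(raw[[col_b]]),
    mi_code = as.character(raw[[col_mi]]),
    source_db = if (!is.na(col_src)) as.character(raw[[col_src]]) else NA_character_,
    confidence = conf
  )

  n0 <- nrow(edges)
  if (!is.null(mi_filter)) edges <- filter(edges, .data$mi_code %in% mi_filter)
  if (!is.null(min_confidence)) {
    edges <- filter(edges, !is.na(.data$confidence) &
                      .data$confidence >= min_confidence)
  }
  edges <- filter(edges, .data$gene_a != .data$gene_b)
  # canonical undirected identity: (a, b) == (b, a)
  a <- pmin(edges$gene_a, edges$gene_b)
  b <- pmax(edges$gene_a, edges$gene_b)
  edges$gene_a <- a
  edges$gene_b <- b
  edges <- distinct(edges, .data$gene_a, .data$gene_b, .keep_all = TRUE)
  edges <- arrange(edges, .data$gene_a, .data$gene_b)
  inform(sprintf("read_ppi_table: %d rows in, %d undirected edges retained (%d dropped)",
                 n0, nrow(edges), n0 - nrow(edges)))
  edges
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors (set id -> member symbols).
#'   Duplicate members are collapsed; empty sets are an error.
#' @param name Collection name.
#' @param universe_hint Optional character vector of genes suggesting a
#'   testing universe for the collection.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, name = "collection", universe_hint = NULL) {
  stopifnot(is.list(sets))
  if (length(sets) > 0 && is.null(names(sets))) {
    abort("gene sets must be named")
  }
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (any(lengths(sets) == 0)) {
    abort(sprintf("empty gene set(s): %s",
                  paste(names(sets)[lengths(sets) == 0], collapse = ", ")),
          class = "dgnet_format_error")
  }
  structure(list(name = name, sets = sets, universe_hint = universe_hint),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection '%s': %d sets, %d distinct genes>\n",
              x$name, length(x$sets), length(unique(unlist(x$sets)))))
  invisible(x)
}

#' @method as_tibble gene_set_collection
#' @export
as_tibble.gene_set_collection <- function(x, ...) {
  tibble(set_id = rep(names(x$sets), lengths(x$sets)),
         gene = unlist(x$sets, use.names = FALSE))
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated fields
#' `set-id<TAB>description<TAB>member1<TAB>member2...`. Duplicate members
#' within a set are collapsed.
#'
#' @param path Path to a GMT file.
#' @param name Collection name; defaults to the file name.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path, name = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warn(sprintf("GMT file %s contains no sets", path))
    return(gene_set_collection(setNames(list(), character(0)), name = name))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3)
  if (length(short) > 0) {
    abort(sprintf("GMT line %d of %s has fewer than 3 fields", short[1], path),
          class = "dgnet_format_error")
  }
  sets <- lapply(parts, function(p) unique(p[-c(1, 2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  gene_set_collection(sets, name = name)
}

#' Write a gene-set collection as GMT
#'
#' @param collection A [gene_set_collection()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(id) {
    paste(c(id, "na", collection$sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read long-format expression records
#'
#' Expects a delimited file (TSV or CSV by extension) with columns `gene`,
#' `region`, `stage`, `rpkm`; replicate measurements appear as repeated
#' (gene, region, stage) rows.
#'
#' @param path Path to the file.
#' @return A tibble with columns `gene`, `region`, `stage`, `rpkm`.
#' @export
read_expression_long <- function(path) {
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE)) readr::read_csv else readr::read_tsv
  x <- reader(path, show_col_types = FALSE, progress = FALSE)
  need <- c("gene", "region", "stage", "rpkm")
  names(x) <- tolower(names(x))
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(sprintf("expression table %s is missing column(s): %s",
                  path, paste(miss, collapse = ", ")),
          class = "dgnet_format_error")
  }
  x <- select(x, all_of(need))
  x$rpkm <- as.numeric(x$rpkm)
  if (any(!is.finite(x$rpkm)) || any(x$rpkm < 0)) {
    abort("expression table contains negative or non-finite RPKM values",
          class = "dgnet_validation_error")
  }
  as_tibble(x)
}

#' Write and read result tables as TSV
#'
#' Results are written as TSV with the column order of the input table and
#' doubles serialized at 17 significant digits (full round-trip precision),
#' so `read_results(write_results(x))` reproduces `x` exactly and a second
#' round-trip is byte-identical to the first.
#'
#' @param results A data frame of results.
#' @param path Output path.
#' @return `path` invisibly (for `write_results`); a tibble (for
#'   `read_results`).
#' @export
write_results <- function(results, path) {
  out <- as_tibble(results)
  is_dbl <- vapply(out, is.double, logical(1))
  out[is_dbl] <- lapply(out[is_dbl], function(x) {
    ifelse(is.na(x), NA_character_, sprintf("%.17g", x))
  })
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  # base read.delim: strtod parsing is correctly rounded, so 17-digit
  # serialized doubles are recovered bit-exactly
  as_tibble(utils::read.delim(path, sep = "\t", header = TRUE,
                              check.names = FALSE,
                              stringsAsFactors = FALSE))
}
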