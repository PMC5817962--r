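# Core containers and I/O.
#
# Counts travel as plain integer matrices (genes x samples, dimnames set),
# designs as two-column data frames (sample, condition) -- the same
# lightweight representation edgeR-style pipelines use.

#' Read a gene-by-sample count table
#'
#' Two dialects are supported. `matrix_tsv` is a single tab-separated file
#' with a header row of sample identifiers and gene identifiers in the first
#' column. `htseq_pair` is the per-sample two-column (gene, count) format
#' written by htseq-count: `path` is then a vector of file paths, one per
#' sample, merged on gene identifier; the trailing summary rows whose gene id
#' starts with `"__"` (e.g. `__no_feature`) are dropped, with a message
#' reporting how many.
#'
#' Counts must be non-negative integers; anything else (including numbers
#' with thousands separators) is a parse error naming the offending gene and
#' sample. Gene order of `matrix_tsv` input is preserved; `htseq_pair` output
#' is sorted lexicographically by gene id so that the result does not depend
#' on the row order of the individual files.
#'
#' @param path File path (`matrix_tsv`) or character vector of file paths
#'   (`htseq_pair`).
#' @param dialect `"matrix_tsv"` or `"htseq_pair"`.
#' @return Integer matrix of counts with gene ids as row names and sample ids
#'   as column names.
#' @export
read_count_table <- function(path, dialect = c("matrix_tsv", "htseq_pair")) {
  dialect <- match.arg(dialect)
  if (!all(file.exists(path))) {
    stop("file not found: ", paste(path[!file.exists(path)], collapse = ", "))
  }
  if (dialect == "matrix_tsv") {
    if (length(path) != 1L) stop("dialect 'matrix_tsv' expects a single file")
    tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                             check.names = FALSE, colClasses = "character",
                             stringsAsFactors = FALSE)
    if (ncol(tab) < 2L) stop("count table needs a gene column and >= 1 sample column")
    gene_ids <- tab[[1L]]
    sample_ids <- colnames(tab)[-1L]
    counts <- matrix(0L, nrow = nrow(tab), ncol = length(sample_ids),
                     dimnames = list(gene_ids, sample_ids))
    for (j in seq_along(sample_ids)) {
      counts[, j] <- .parse_count_column(tab[[j + 1L]], gene_ids, sample_ids[j])
    }
  } else {
    sample_ids <- sub("\\.[^.]*$", "", basename(path))
    per_file <- lapply(seq_along(path), function(i) {
      tab <- utils::read.delim(path[i], header = FALSE, sep = "\t",
                               colClasses = "character",
                               stringsAsFactors = FALSE)
      if (ncol(tab) != 2L) stop("htseq file ", path[i], " is not two-column")
      summary_rows <- startsWith(tab[[1L]], "__")
      if (any(summary_rows)) {
        message("dropped ", sum(summary_rows), " htseq summary row(s) from ",
                basename(path[i]))
        tab <- tab[!summary_rows, , drop = FALSE]
      }
      y <- .parse_count_column(tab[[2L]], tab[[1L]], sample_ids[i])
      names(y) <- tab[[1L]]
      y
    })
    genes <- sort(names(per_file[[1L]]))
    for (i in seq_along(per_file)[-1L]) {
      gi <- sort(names(per_file[[i]]))
      if (!identical(genes, gi)) {
        divergent <- c(setdiff(genes, gi), setdiff(gi, genes))[1L]
        stop("gene sets differ across htseq files (first divergent id: ",
             divergent, ")")
      }
    }
    counts <- vapply(per_file, function(y) y[genes], numeric(length(genes)))
    dimnames(counts) <- list(genes, sample_ids)
    storage.mode(counts) <- "integer"
    gene_ids <- genes
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicated gene id: ", rownames(counts)[duplicated(rownames(counts))][1L])
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicated sample id: ", colnames(counts)[duplicated(colnames(counts))][1L])
  }
  counts
}

# Strict parse of one column of counts: non-negative integers only,
# no thousands separators, no decimals.
.parse_count_column <- function(x, gene_ids, sample_id) {
  ok <- grepl("^[0-9]+$", x)
  if (!all(ok)) {
    bad <- which(!ok)[1L]
    stop("non-integer or negative count '", x[bad], "' at gene ", gene_ids[bad],
         ", sample ", sample_id)
  }
  as.integer(x)
}

#' Read a sample-to-condition design table
#'
#' @param path TSV file with header `sample<TAB>condition`.
#' @return Data frame with character columns `sample` and `condition`.
#' @export
read_study_design <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", stringsAsFactors = FALSE)
  if (!all(c("sample", "condition") %in% colnames(tab))) {
    stop("design table needs columns 'sample' and 'condition'")
  }
  design <- tab[, c("sample", "condition")]
  validate_design(design)
  design
}

#' Validate a study design, optionally against a count matrix
#'
#' Every sample must appear exactly once. When `counts` is supplied the
#' design samples must match its columns.
#'
#' @param design Data frame with columns `sample`, `condition`.
#' @param counts Optional count matrix to check against.
#' @return The design, invisibly.
#' @export
validate_design <- function(design, counts = NULL) {
  if (!is.data.frame(design) || !all(c("sample", "condition") %in% colnames(design))) {
    stop("design must be a data frame with columns 'sample' and 'condition'")
  }
  if (anyDuplicated(design$sample)) {
    stop("sample appears in more than one row: ",
         design$sample[duplicated(design$sample)][1L])
  }
  if (!is.null(counts)) {
    missing <- setdiff(colnames(counts), design$sample)
    if (length(missing)) stop("samples missing from design: ",
                              paste(missing, collapse = ", "))
  }
  invisible(design)
}

# Samples of one condition, in count-matrix column order.
.condition_samples <- function(counts, design, condition) {
  ids <- design$sample[design$condition == condition]
  intersect(colnames(counts), ids)
}

#' Analysis parameters
#'
#' Bundles every tunable threshold of the evaluation pipeline.
#'
#' @param alpha_de BH-adjusted p-value threshold for declaring a gene DE
#'   (default 0.05).
#' @param alpha_reference Stringent threshold defining the full-data power
#'   reference list (default 1e-4).
#' @param alpha_truth Stringent threshold defining the TPR/FPR truth list
#'   (default 1e-3).
#' @param alpha_fpr Threshold used in FPR experiments (default 0.01).
#' @param n_repetitions Subsampled datasets per grid cell (default 45).
#' @param n_fpr_repetitions Repetitions for TPR/FPR and mock-comparison
#'   experiments (default 30).
#' @param replicate_grid Replicate numbers evaluated (default 2:7).
#' @param depth_grid Library sizes (reads per sample) evaluated.
#' @param dispersion_prior_weight Shrinkage weight of the tagwise dispersion
#'   estimator, in pseudo-gene units (default 10).
#' @param master_seed Integer seed from which all per-task seeds are derived.
#' @return A list of class `analysis_params`.
#' @export
analysis_params <- function(alpha_de = 0.05,
                            alpha_reference = 1e-4,
                            alpha_truth = 1e-3,
                            alpha_fpr = 0.01,
                            n_repetitions = 45L,
                            n_fpr_repetitions = 30L,
                            replicate_grid = 2:7,
                            depth_grid = c(2.5e6, 5e6, 7.5e6, 1e7, 1.5e7, 2e7),
                            dispersion_prior_weight = 10,
                            master_seed = 1L) {
  params <- list(alpha_de = alpha_de, alpha_reference = alpha_reference,
                 alpha_truth = alpha_truth, alpha_fpr = alpha_fpr,
                 n_repetitions = as.integer(n_repetitions),
                 n_fpr_repetitions = as.integer(n_fpr_repetitions),
                 replicate_grid = as.integer(replicate_grid),
                 depth_grid = as.numeric(depth_grid),
                 dispersion_prior_weight = dispersion_prior_weight,
                 master_seed = as.integer(master_seed))
  for (a in c("alpha_de", "alpha_reference", "alpha_truth", "alpha_fpr")) {
    if (!is.numeric(params[[a]]) || params[[a]] <= 0 || params[[a]] > 1) {
      stop(a, " must lie in (0, 1]")
    }
  }
  if (params$n_repetitions < 1L) stop("n_repetitions must be >= 1")
  if (params$n_fpr_repetitions < 1L) stop("n_fpr_repetitions must be >= 1")
  if (!length(params$replicate_grid) || any(params$replicate_grid < 2L)) {
    stop("replicate_grid must be non-empty with values >= 2")
  }
  if (!length(params$depth_grid) || any(params$depth_grid <= 0)) {
    stop("depth_grid must be non-empty with positive values")
  }
  if (params$dispersion_prior_weight < 0) stop("dispersion_prior_weight must be >= 0")
  structure(params, class = "analysis_params")
}

#' Read analysis parameters from a flat key-value config file
#'
#' One `key<TAB>value` (or `key=value`) pair per line, keys mirroring the
#' [analysis_params()] argument names; `replicate_grid` and `depth_grid`
#' accept comma-separated values. Unknown keys are an error so that typos in
#' threshold names are caught rather than silently ignored. Blank lines and
#' lines starting with `#` are skipped.
#'
#' @param path Config file path.
#' @return An `analysis_params` object.
#' @export
read_analysis_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  known <- names(formals(analysis_params))
  args <- list()
  for (line in lines) {
    parts <- strsplit(line, "[=\t]", perl = TRUE)[[1L]]
    parts <- trimws(parts)
    if (length(parts) != 2L) stop("malformed config line: '", line, "'")
    key <- parts[1L]
    if (!key %in% known) stop("unknown config key: '", key, "'")
    value <- as.numeric(strsplit(parts[2L], ",")[[1L]])
    if (anyNA(value)) stop("non-numeric value for config key '", key, "'")
    args[[key]] <- value
  }
  do.call(analysis_params, args)
}

#' Write / read a gene set as a plain text file
#'
#' One gene id per line, LF line endings, sorted lexicographically (fixed
#' `C`-locale order) so output is deterministic. An empty set yields an empty
#' (0-byte) file.
#'
#' @param genes Character vector of gene ids.
#' @param path Output file.
#' @return `write_gene_set` returns `path` invisibly; `read_gene_set` the
#'   character vector of ids.
#' @export
write_gene_set <- function(genes, path) {
  genes <- unique(as.character(genes))
  if (length(genes) && any(!nzchar(genes))) stop("gene ids must be non-empty strings")
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(genes)) {
    writeLines(.sort_c(genes), con, sep = "\n", useBytes = TRUE)
  }
  invisible(path)
}

#' @rdname write_gene_set
#' @export
read_gene_set <- function(path) {
  if (file.size(path) == 0) return(character(0))
  readLines(path)
}

# Locale-independent lexicographic sort.
.sort_c <- function(x) {
  old <- Sys.getlocale("LC_COLLATE")
  on.exit(Sys.setlocale("LC_COLLATE", old), add = TRUE)
  Sys.setlocale("LC_COLLATE", "C")
  sort(x, method = "radix")
}

#' Write an indicator table as TSV
#'
#' Rows are ordered by replicate number `r` ascending, then `depth`
#' ascending, for deterministic output.
#'
#' @param table Data frame containing at least columns `r` and `depth`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_indicator_table <- function(table, path) {
  if (!all(c("r", "depth") %in% colnames(table))) {
    stop("indicator table needs columns 'r' and 'depth'")
  }
  table <- table[order(table$r, table$depth), , drop = FALSE]
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a count matrix as TSV
#'
#' Inverse of [read_count_table()] with dialect `matrix_tsv`: header
#' `gene<TAB>sample1...`, counts as plain integers.
#'
#' @param counts Integer count matrix with dimnames.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path) {
  tab <- data.frame(gene = rownames(counts), counts, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a JSON run summary
#'
#' Records the analysis parameters, master seed and per-cell indicator values
#' of a grid run in one machine-readable file.
#'
#' @param params An `analysis_params` object.
#' @param cells Output of [run_grid()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_run_summary <- function(params, cells, path) {
  cell_rows <- lapply(cells, function(cell) {
    list(r = cell$r, depth = cell$depth, repetition = cell$repetition,
         seed = cell$seed, dispersion_mode = cell$dispersion_mode,
         n_de = length(cell$de_set))
  })
  summary <- list(params = unclass(params),
                  seeds = list(master_seed = params$master_seed),
                  cells = cell_rows)
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Derive a task seed from a master seed and a counter
#'
#' Deterministic integer mixing so that every (stage, grid-cell, repetition)
#' combination gets its own reproducible RNG seed without global state; the
#' result always lies in `[0, 2^31 - 2]`.
#'
#' @param ... Integers: master seed followed by counter components (stage
#'   tag, grid indices, repetition index, ...).
#' @return A single integer seed.
#' @export
derive_seed <- function(...) {
  xs <- as.numeric(c(...))
  if (anyNA(xs)) stop("seed components must be numbers")
  m <- 2147483647
  s <- 104729
  for (x in xs) {
    s <- (s * 69069 + (abs(x) %% m) + 1) %% m
  }
  as.integer(s)
}
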