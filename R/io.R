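#' Gene set constructor
#'
#' A gene set is a character vector of unique, uppercased gene symbols with a
#' `name` attribute. Symbols are uppercased and deduplicated on construction;
#' an empty set is an error.
#'
#' @param symbols character vector of gene symbols.
#' @param name set name.
#' @return an object of class `gene_set`.
#' @export
gene_set <- function(symbols, name = "gene_set") {
  symbols <- toupper(trimws(as.character(symbols)))
  symbols <- symbols[nzchar(symbols) & !is.na(symbols)]
  symbols <- unique(symbols)
  if (length(symbols) == 0L) stop_("gene set '%s' is empty", name)
  structure(symbols, name = name, class = c("gene_set", "character"))
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set '%s': %d symbols>\n", attr(x, "name"), length(x)))
  cat(strwrap(paste(unclass(x), collapse = ", "), width = 76), sep = "\n")
  invisible(x)
}

#' Expression matrix constructor
#'
#' Wraps a numeric genes x samples matrix, validating identifiers and the
#' declared kind of values it holds.
#'
#' @param values numeric matrix, genes in rows (rownames = gene symbols),
#'   samples in columns (colnames = sample ids).
#' @param value_kind one of `"raw_counts"`, `"normalized"`, `"log2"`.
#' @return the matrix with a `value_kind` attribute, class `expr_matrix`.
#' @export
expression_matrix <- function(values, value_kind = c("raw_counts", "normalized", "log2")) {
  value_kind <- match.arg(value_kind)
  if (!is.matrix(values) || !is.numeric(values)) stop_("values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(values))) stop_("duplicate gene ids in expression matrix")
  if (anyDuplicated(colnames(values))) stop_("duplicate sample ids in expression matrix")
  if (value_kind == "raw_counts") {
    if (anyNA(values)) stop_("NA/NaN values not allowed in raw counts")
    if (any(values < 0)) stop_("negative values not allowed in raw counts")
  }
  structure(values, value_kind = value_kind, class = c("expr_matrix", class(values)))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix: %d genes x %d samples, %s>\n",
              nrow(x), ncol(x), value_kind(x)))
  invisible(x)
}

#' Kind of values stored in an expression matrix
#' @param x a matrix, possibly created by [expression_matrix()].
#' @return `"raw_counts"`, `"normalized"` or `"log2"` (default `"raw_counts"`
#'   when the attribute is absent).
#' @export
value_kind <- function(x) attr(x, "value_kind") %||% "raw_counts"

# subset an expr_matrix without losing its value_kind
#' @export
`[.expr_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out))
    out <- structure(out, value_kind = attr(x, "value_kind"),
                     class = c("expr_matrix", class(unclass(out))))
  out
}

#' Read a paired clinical measurements table
#'
#' Parses a CSV of one row per patient with paired biopsy (Bx) and surgical
#' (Sx) Ki67 and ROR measurements plus covariates. `"ND"` or an empty field
#' denotes a missing ROR value; `"<30"` denotes serum estradiol below the
#' 30 pg/mL detection limit (stored as 30 with `e2_below_detection = TRUE`).
#'
#' @param path CSV file with header
#'   `patient_id,age,tumour_size,histology,grade,interval_days,e2_baseline,e2_post,ki67_bx,ki67_sx,ror_bx,ror_sx`.
#' @return a data.frame with one row per patient; missing values are `NA`,
#'   never zero-filled.
#' @export
read_clinical_table <- function(path) {
  raw <- read.csv(path, colClasses = "character", check.names = FALSE,
                  strip.white = TRUE)
  required <- c("patient_id", "age", "tumour_size", "histology", "grade",
                "interval_days", "e2_baseline", "e2_post",
                "ki67_bx", "ki67_sx", "ror_bx", "ror_sx")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    stop_("clinical table missing column(s): %s", paste(missing_cols, collapse = ", "))
  if (nrow(raw) == 0L) {
    out <- data.frame(patient_id = character(), age = numeric(),
                      tumour_size = numeric(), histology = integer(),
                      grade = integer(), interval_days = numeric(),
                      e2_baseline = numeric(), e2_below_detection = logical(),
                      e2_post = numeric(), ki67_bx = numeric(),
                      ki67_sx = numeric(), ror_bx = numeric(),
                      ror_sx = numeric(), stringsAsFactors = FALSE)
    return(out)
  }
  if (anyDuplicated(raw$patient_id))
    stop_("duplicate patient_id: %s",
          paste(unique(raw$patient_id[duplicated(raw$patient_id)]), collapse = ", "))

  num <- function(col, allow_missing = FALSE) {
    x <- raw[[col]]
    miss <- is.na(x) | x == "" | toupper(x) == "ND"
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!miss & is.na(out))
    if (length(bad))
      stop_("unparsable value '%s' in row %d, column '%s'", x[bad[1]], bad[1], col)
    if (any(miss) && !allow_missing)
      stop_("missing value in required column '%s' (row %d)", col, which(miss)[1])
    out[miss] <- NA_real_
    out
  }
  e2 <- function(col) {
    x <- raw[[col]]
    below <- grepl("^<", x)
    x2 <- sub("^<", "", x)
    miss <- is.na(x2) | x2 == "" | toupper(x2) == "ND"
    val <- suppressWarnings(as.numeric(x2))
    bad <- which(!miss & is.na(val))
    if (length(bad))
      stop_("unparsable value '%s' in row %d, column '%s'", x[bad[1]], bad[1], col)
    val[miss] <- NA_real_
    list(value = val, below = below)
  }

  e2b <- e2("e2_baseline"); e2p <- e2("e2_post")
  out <- data.frame(
    patient_id = raw$patient_id,
    age = num("age"),
    tumour_size = num("tumour_size"),
    histology = as.integer(num("histology")),
    grade = as.integer(num("grade")),
    interval_days = num("interval_days"),
    e2_baseline = e2b$value,
    e2_below_detection = e2b$below,
    e2_post = e2p$value,
    ki67_bx = num("ki67_bx"),
    ki67_sx = num("ki67_sx"),
    ror_bx = num("ror_bx", allow_missing = TRUE),
    ror_sx = num("ror_sx", allow_missing = TRUE),
    stringsAsFactors = FALSE
  )
  if (any(out$ki67_bx < 0, na.rm = TRUE) || any(out$ki67_sx < 0, na.rm = TRUE))
    stop_("negative Ki67 value")
  ror <- c(out$ror_bx, out$ror_sx)
  if (any(ror < 0 | ror > 100, na.rm = TRUE))
    stop_("ROR values must lie in [0, 100]")
  out
}

#' Write a clinical table back to CSV
#'
#' Inverse of [read_clinical_table()]: missing ROR fields are written as
#' `"ND"` and below-detection estradiol as `"<limit>"` so that a write/read
#' cycle reproduces the table exactly.
#'
#' @param records data.frame from [read_clinical_table()] or
#'   [generate_clinical_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_clinical_table <- function(records, path) {
  fmt_e2 <- function(v, below) {
    s <- num_to_string(v)
    below <- rep_len(below, length(v))
    ifelse(below, paste0("<", s), s)
  }
  fmt_na <- function(v) ifelse(is.na(v), "ND", num_to_string(v))
  df <- data.frame(
    patient_id = records$patient_id,
    age = num_to_string(records$age),
    tumour_size = num_to_string(records$tumour_size),
    histology = records$histology,
    grade = records$grade,
    interval_days = num_to_string(records$interval_days),
    e2_baseline = fmt_e2(records$e2_baseline, records$e2_below_detection),
    e2_post = fmt_e2(records$e2_post, FALSE),
    ki67_bx = num_to_string(records$ki67_bx),
    ki67_sx = num_to_string(records$ki67_sx),
    ror_bx = fmt_na(records$ror_bx),
    ror_sx = fmt_na(records$ror_sx),
    stringsAsFactors = FALSE, check.names = FALSE
  )
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read gene lists from TXT or GMT
#'
#' TXT holds one symbol per line and yields a single [gene_set()] named after
#' the file; GMT holds `name<TAB>description<TAB>symbol...` per line and
#' yields a named list of gene sets.
#'
#' @param path file path; format chosen by the `.gmt` extension.
#' @return a `gene_set` (TXT) or named list of `gene_set`s (GMT).
#' @export
read_gene_list <- function(path) {
  if (tolower(tools::file_ext(path)) == "gmt") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) stop_("empty GMT file: %s", path)
    sets <- lapply(lines, function(ln) {
      parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(parts) < 3L) stop_("malformed GMT line: %s", substr(ln, 1, 60))
      gene_set(parts[-(1:2)], name = parts[1])
    })
    names(sets) <- vapply(sets, attr, character(1), "name")
    sets
  } else {
    symbols <- readLines(path, warn = FALSE)
    symbols <- symbols[nzchar(trimws(symbols))]
    gene_set(symbols, name = tools::file_path_sans_ext(basename(path)))
  }
}

#' Write a gene set (one symbol per line)
#' @param genes a [gene_set()] or character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}

#' Read an expression matrix plus sample sheet
#'
#' The matrix is either a TSV (genes in rows, first column = gene id, header =
#' sample ids) or a MatrixMarket file accompanied by plain-text row/column
#' name files. The sample sheet is a CSV with columns
#' `sample_id,patient_id,timepoint,group` (`sample,patient,...` accepted).
#' Matrix columns are reordered to the sheet order.
#'
#' @param matrix_path TSV or `.mtx` file.
#' @param samples_path sample sheet CSV.
#' @param row_names,col_names name files for MatrixMarket input; default
#'   `<matrix_path>.rownames` / `<matrix_path>.colnames`.
#' @param value_kind declared kind of the values (see [expression_matrix()]).
#' @return `list(matrix = expr_matrix, meta = data.frame)`.
#' @export
read_expression <- function(matrix_path, samples_path,
                            row_names = paste0(matrix_path, ".rownames"),
                            col_names = paste0(matrix_path, ".colnames"),
                            value_kind = "raw_counts") {
  if (tolower(tools::file_ext(matrix_path)) == "mtx") {
    m <- as.matrix(Matrix::readMM(matrix_path))
    rn <- readLines(row_names, warn = FALSE)
    cn <- readLines(col_names, warn = FALSE)
    if (length(rn) != nrow(m) || length(cn) != ncol(m))
      stop_("row/column name files do not match matrix dimensions")
    dimnames(m) <- list(rn, cn)
  } else {
    df <- read.delim(matrix_path, check.names = FALSE, row.names = 1)
    m <- as.matrix(df)
  }
  storage.mode(m) <- "double"
  if (value_kind == "raw_counts" && anyNA(m))
    stop_("NaN/NA in raw count matrix %s", matrix_path)

  meta <- read.csv(samples_path, stringsAsFactors = FALSE, strip.white = TRUE)
  alias <- c(sample = "sample_id", patient = "patient_id")
  for (a in names(alias))
    if (a %in% names(meta) && !(alias[[a]] %in% names(meta)))
      names(meta)[names(meta) == a] <- alias[[a]]
  need <- c("sample_id", "patient_id", "timepoint", "group")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop_("sample sheet missing column(s): %s", paste(miss, collapse = ", "))
  unknown <- setdiff(meta$sample_id, colnames(m))
  if (length(unknown))
    stop_("sample sheet references sample(s) absent from matrix: %s",
          paste(unknown, collapse = ", "))
  m <- m[, meta$sample_id, drop = FALSE]
  list(matrix = expression_matrix(m, value_kind), meta = meta)
}

#' Write an expression matrix (TSV) and optional sample sheet
#' @param mat genes x samples matrix.
#' @param matrix_path output TSV path (first column `gene_id`).
#' @param meta optional sample sheet data.frame.
#' @param samples_path output CSV path for `meta`.
#' @return `matrix_path`, invisibly.
#' @export
write_expression <- function(mat, matrix_path, meta = NULL, samples_path = NULL) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(meta)) {
    if (is.null(samples_path)) stop_("samples_path required when meta is given")
    write.csv(meta, samples_path, row.names = FALSE, quote = FALSE)
  }
  invisible(matrix_path)
}

#' Read a survival table
#' @param path CSV with columns `sample_id,time,event` and optionally `group`.
#' @return data.frame with positive times and 0/1 events.
#' @export
read_survival_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE)
  if ("sample" %in% names(df) && !("sample_id" %in% names(df)))
    names(df)[names(df) == "sample"] <- "sample_id"
  need <- c("sample_id", "time", "event")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_("survival table missing column(s): %s", paste(miss, collapse = ", "))
  if (any(df$time <= 0)) stop_("survival times must be positive")
  if (!all(df$event %in% c(0, 1))) stop_("event must be 0 (censored) or 1 (event)")
  df
}

#' Packaged study fixtures
#'
#' Accessors for the clinical table and derived gene signatures shipped with
#' the package: the 19-patient paired Ki67/ROR table, the 30-gene pre-treatment
#' (core biopsy) signature with its 12-gene array-matched subset, and the
#' 45-gene post-treatment (surgical) signature with its 30-gene subset shared
#' with the DREAM-repressed gene list.
#'
#' @param which for `presto_signature`: one of `"core30"`, `"core12"`,
#'   `"surg45"`, `"dream30"`.
#' @return `presto_clinical()` returns the clinical data.frame;
#'   `presto_signature()` returns a [gene_set()].
#' @export
presto_clinical <- function() {
  read_clinical_table(system.file("extdata", "presto_clinical.csv",
                                  package = "e2response", mustWork = TRUE))
}

#' @rdname presto_clinical
#' @export
presto_signature <- function(which = c("core30", "core12", "surg45", "dream30")) {
  which <- match.arg(which)
  file <- switch(which,
                 core30 = "presto30_core.txt",
                 core12 = "presto30_core_arraymatched12.txt",
                 surg45 = "presto45_surg.txt",
                 dream30 = "presto45_surg_dream30.txt")
  read_gene_list(system.file("extdata", file, package = "e2response", mustWork = TRUE))
}
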