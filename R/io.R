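#' Read a feature table from BIOM (HDF5 or JSON) or TSV
#'
#' TSV tables follow the dominant BIOM-TSV convention: features as rows,
#' samples as columns, tab-separated, with the first header cell `#OTU ID`
#' tolerated (as is a leading `# Constructed from biom file` comment line).
#' HDF5 tables follow the BIOM 2.1 layout; JSON tables the BIOM 1.0 layout.
#'
#' @param path Path to an existing file.
#' @param format_hint One of `"auto"`, `"tsv"`, `"biom"`. With `"auto"` the
#'   format is sniffed (HDF5 signature, then leading `{` for JSON, else TSV).
#' @param transpose Logical; set `TRUE` for TSV files written with samples
#'   as rows.
#' @return A [feature_table()] (samples x features).
#' @export
read_feature_table <- function(path, format_hint = c("auto", "tsv", "biom"),
                               transpose = FALSE) {
  format_hint <- match.arg(format_hint)
  if (!file.exists(path)) stop("no such file: ", path)
  fmt <- format_hint
  if (fmt == "auto") {
    fmt <- if (isTRUE(suppressWarnings(rhdf5::H5Fis_hdf5(path)))) {
      "hdf5"
    } else if (startsWith(trimws(readChar(path, 1L, useBytes = TRUE)), "{")) {
      "json"
    } else "tsv"
  } else if (fmt == "biom") {
    fmt <- if (isTRUE(suppressWarnings(rhdf5::H5Fis_hdf5(path)))) "hdf5" else "json"
  }
  switch(fmt,
         hdf5 = read_biom_hdf5(path),
         json = read_biom_json(path),
         tsv  = read_table_tsv(path, transpose = transpose))
}

read_table_tsv <- function(path, transpose = FALSE) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) stop("empty TSV table: ", path)
  # optional leading comment line before the header
  if (startsWith(lines[1], "#") && length(lines) > 1 &&
      startsWith(lines[2], "#OTU ID")) {
    lines <- lines[-1]
  }
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(header) < 1) {
    stop("malformed TSV header (line 1): ", lines[1])
  }
  sample_ids <- header[-1]
  body <- lines[-1]
  body <- body[nzchar(body)]
  feature_ids <- character(length(body))
  counts <- matrix(0, nrow = length(body), ncol = length(sample_ids))
  for (i in seq_along(body)) {
    fields <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) != length(header)) {
      stop(sprintf("malformed TSV row at line %d: expected %d fields, found %d: %s",
                   i + 1L, length(header), length(fields),
                   substr(body[i], 1, 60)))
    }
    feature_ids[i] <- fields[1]
    vals <- suppressWarnings(as.numeric(fields[-1]))
    bad <- which(is.na(vals) | vals < 0 | vals != round(vals))
    if (length(bad) > 0) {
      stop(sprintf(
        "invalid count '%s' at line %d (feature '%s'), column %d (sample '%s'): counts must be non-negative integers",
        fields[-1][bad[1]], i + 1L, fields[1], bad[1] + 1L,
        sample_ids[bad[1]]))
    }
    counts[i, ] <- vals
  }
  rownames(counts) <- feature_ids
  colnames(counts) <- sample_ids
  if (transpose) counts <- t(counts)
  feature_table(t(counts))  # stored samples x features
}

read_biom_hdf5 <- function(path) {
  ids_obs <- as.character(rhdf5::h5read(path, "observation/ids"))
  ids_smp <- as.character(rhdf5::h5read(path, "sample/ids"))
  data <- as.numeric(rhdf5::h5read(path, "sample/matrix/data"))
  indices <- as.integer(rhdf5::h5read(path, "sample/matrix/indices"))
  indptr <- as.integer(rhdf5::h5read(path, "sample/matrix/indptr"))
  counts <- matrix(0, nrow = length(ids_smp), ncol = length(ids_obs),
                   dimnames = list(ids_smp, ids_obs))
  for (j in seq_along(ids_smp)) {
    lo <- indptr[j] + 1L
    hi <- indptr[j + 1L]
    if (hi >= lo) {
      counts[j, indices[lo:hi] + 1L] <- data[lo:hi]
    }
  }
  feature_table(counts)
}

read_biom_json <- function(path) {
  b <- biomformat::read_biom(path)
  m <- as(biomformat::biom_data(b), "matrix")  # features x samples
  feature_table(t(m))
}

#' Write a feature table to BIOM HDF5 or TSV
#'
#' The TSV writer emits the features-as-rows dialect with a `#OTU ID`
#' header; the HDF5 writer emits the BIOM 2.1 layout (CSR under
#' `observation/matrix`, CSC under `sample/matrix`). Both round-trip
#' exactly through [read_feature_table()].
#'
#' @param table A [feature_table()].
#' @param path Output path.
#' @param format_hint `"tsv"` or `"hdf5"`.
#' @return Invisibly, `path`.
#' @export
write_feature_table <- function(table, path, format_hint = c("tsv", "hdf5")) {
  format_hint <- match.arg(format_hint)
  x <- as_feature_table(table)
  if (format_hint == "tsv") {
    m <- t(unclass(x))  # features x samples
    header <- paste(c("#OTU ID", colnames(m)), collapse = "\t")
    body <- if (nrow(m) > 0) {
      paste(rownames(m),
            apply(format(m, scientific = FALSE, trim = TRUE), 1,
                  paste, collapse = "\t"),
            sep = if (ncol(m) > 0) "\t" else "")
    } else character(0)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(header, body), con)
  } else {
    write_biom_hdf5(x, path)
  }
  invisible(path)
}

write_biom_hdf5 <- function(x, path) {
  m <- unclass(x)  # samples x features
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  for (g in c("observation", "observation/matrix", "observation/metadata",
              "observation/group-metadata", "sample", "sample/matrix",
              "sample/metadata", "sample/group-metadata")) {
    rhdf5::h5createGroup(path, g)
  }
  rhdf5::h5write(colnames(m) %||% character(0), path, "observation/ids")
  rhdf5::h5write(rownames(m) %||% character(0), path, "sample/ids")
  # CSC by sample (features indexed within each sample)
  csc <- sparse_triplets(m)
  rhdf5::h5write(csc$data, path, "sample/matrix/data")
  rhdf5::h5write(csc$indices, path, "sample/matrix/indices")
  rhdf5::h5write(csc$indptr, path, "sample/matrix/indptr")
  # CSR by observation
  csr <- sparse_triplets(t(m))
  rhdf5::h5write(csr$data, path, "observation/matrix/data")
  rhdf5::h5write(csr$indices, path, "observation/matrix/indices")
  rhdf5::h5write(csr$indptr, path, "observation/matrix/indptr")
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute("No Table ID", fid, "id")
  rhdf5::h5writeAttribute("OTU table", fid, "type")
  rhdf5::h5writeAttribute("http://biom-format.org", fid, "format-url")
  rhdf5::h5writeAttribute(c(2L, 1L), fid, "format-version")
  rhdf5::h5writeAttribute(paste0("debloom ", debloom_version()), fid,
                          "generated-by")
  rhdf5::h5writeAttribute(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), fid,
                          "creation-date")
  rhdf5::h5writeAttribute(c(ncol(m), nrow(m)), fid, "shape")
  rhdf5::h5writeAttribute(sum(m != 0), fid, "nnz")
  rhdf5::H5Fclose(fid)
  invisible(path)
}

# row-major sparse encoding of a samples x features slice:
# per row, the nonzero (index, value) pairs; indptr has length nrow+1
sparse_triplets <- function(m) {
  data <- numeric(0); indices <- integer(0); indptr <- integer(nrow(m) + 1L)
  for (i in seq_len(nrow(m))) {
    nz <- which(m[i, ] != 0)
    data <- c(data, m[i, nz])
    indices <- c(indices, nz - 1L)
    indptr[i + 1L] <- length(indices)
  }
  list(data = data, indices = as.integer(indices), indptr = indptr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

debloom_version <- function() {
  as.character(utils::packageVersion("debloom"))
}

#' Read and write sequence catalogs (FASTA)
#'
#' A sequence catalog is a named character vector of uppercase DNA
#' sequences over `{A,C,G,T,N}`, in file order. The identifier is the
#' first whitespace-delimited token of the FASTA header. Lowercase input
#' is uppercased on read.
#'
#' @param path FASTA file path.
#' @return `read_fasta()`: a named character vector.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  bad <- !grepl("^[ACGTN]+$", seqs)
  if (any(bad)) {
    stop("non-DNA characters in sequence(s): ",
         paste(utils::head(ids[bad], 5), collapse = ", "))
  }
  names(seqs) <- ids
  seqs
}

#' @rdname read_fasta
#' @param catalog Named character vector of DNA sequences.
#' @param width Line-wrap width for sequence lines.
#' @return `write_fasta()`: invisibly, `path`.
#' @export
write_fasta <- function(catalog, path, width = 80L) {
  if (is.null(names(catalog)) || any(!nzchar(names(catalog)))) {
    stop("every sequence needs a non-empty identifier")
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(catalog)) {
    writeLines(paste0(">", names(catalog)[i]), con)
    s <- toupper(catalog[[i]])
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read per-sample metadata
#'
#' Reads a TSV with a header row into the canonical metadata frame with
#' columns `sample_id`, `study_id`, `condition`, `subject_id`, `day`,
#' `age_category`. Source column names are configurable through `columns`.
#' `condition` is normalized case-insensitively to `frozen` /
#' `room_temperature`; columns other than `sample_id` and `study_id` may
#' be absent and are filled with `NA`.
#'
#' @param path TSV file path.
#' @param columns Named character vector mapping canonical names to the
#'   file's column names.
#' @param required Canonical column names that must be present.
#' @return A data.frame of sample metadata.
#' @export
read_metadata <- function(path,
                          columns = c(sample_id = "sample_id",
                                      study_id = "study_id",
                                      condition = "condition",
                                      subject_id = "subject_id",
                                      day = "day",
                                      age_category = "age_category"),
                          required = c("sample_id", "study_id")) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- read_annotation_tsv(path)
  defaults <- c(sample_id = "sample_id", study_id = "study_id",
                condition = "condition", subject_id = "subject_id",
                day = "day", age_category = "age_category")
  defaults[names(columns)] <- columns
  columns <- defaults
  missing_req <- required[!columns[required] %in% names(raw)]
  if (length(missing_req) > 0) {
    stop("metadata is missing required column(s): ",
         paste(columns[missing_req], collapse = ", "))
  }
  out <- data.frame(row.names = NULL, stringsAsFactors = FALSE,
                    sample_id = raw[[columns["sample_id"]]])
  pick <- function(cn) {
    if (columns[cn] %in% names(raw)) raw[[columns[cn]]] else NA_character_
  }
  out$study_id <- pick("study_id")
  out$condition <- normalize_condition(pick("condition"))
  out$subject_id <- pick("subject_id")
  out$day <- suppressWarnings(as.numeric(pick("day")))
  out$age_category <- pick("age_category")
  out$age_category[!is.na(out$age_category) & !nzchar(out$age_category)] <- NA
  if (anyDuplicated(out$sample_id)) {
    stop("duplicate sample_id in metadata: ",
         paste(unique(out$sample_id[duplicated(out$sample_id)]),
               collapse = ", "))
  }
  out
}

# Header-bearing TSV with optional leading "# ..." provenance lines
# (a bare "#Name" first header cell is kept, "# comment" lines are not).
read_annotation_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  while (length(lines) > 0 && grepl("^# ", lines[1])) lines <- lines[-1]
  if (length(lines) == 0) stop("no header row in ", path)
  utils::read.delim(text = lines, header = TRUE, sep = "\t",
                    check.names = FALSE, comment.char = "",
                    colClasses = "character")
}

normalize_condition <- function(x) {
  norm <- tolower(trimws(as.character(x)))
  norm[norm %in% c("rt", "room temperature", "room-temperature",
                   "room_temperature")] <- "room_temperature"
  unknown <- !is.na(norm) & nzchar(norm) &
    !norm %in% c("frozen", "room_temperature")
  if (any(unknown)) {
    stop("unrecognized storage condition value(s): ",
         paste(unique(norm[unknown]), collapse = ", "),
         " (expected 'frozen' or 'room_temperature')")
  }
  norm[!is.na(norm) & !nzchar(norm)] <- NA
  norm
}

#' Read a taxonomy map and extract class-level labels
#'
#' The taxonomy TSV maps feature identifiers to Greengenes-style
#' semicolon-delimited lineage strings (`k__...; p__...; c__...; ...`).
#' The source text is preserved; [lineage_class()] extracts the class
#' rank, returning `"unclassified"` when it is missing or empty.
#'
#' @param path TSV file path with a header row.
#' @param feature_col,lineage_col Column names in the file.
#' @return A data.frame with columns `feature_id` and `lineage`.
#' @export
read_taxonomy <- function(path, feature_col = "feature_id",
                          lineage_col = "lineage") {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- read_annotation_tsv(path)
  for (cn in c(feature_col, lineage_col)) {
    if (!cn %in% names(raw)) {
      stop("taxonomy file is missing required column: ", cn)
    }
  }
  data.frame(feature_id = raw[[feature_col]], lineage = raw[[lineage_col]],
             stringsAsFactors = FALSE)
}

#' @rdname read_taxonomy
#' @param lineage Character vector of lineage strings.
#' @return `lineage_class()`: a character vector of class names.
#' @export
lineage_class <- function(lineage) {
  out <- rep("unclassified", length(lineage))
  ranks <- strsplit(as.character(lineage), ";")
  for (i in seq_along(ranks)) {
    r <- trimws(ranks[[i]])
    hit <- r[startsWith(r, "c__")]
    if (length(hit) >= 1) {
      val <- sub("^c__", "", hit[1])
      if (nzchar(val)) out[i] <- val
    }
  }
  out
}
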