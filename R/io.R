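#' Read a methylation-probe manifest
#'
#' The manifest is a tab-separated file with header columns `probe_id`,
#' `chrom`, `pos`, `cpg_island`. Positions are 1-based inclusive, matching
#' array-annotation convention. Chromosome names are canonicalized to the
#' `chr`-prefixed form (`"23"` and `"X"` both become `"chrX"`); only
#' chr1..chr22 and chrX are modeled, so chrY probes are rejected rather
#' than silently dropped.
#'
#' @param path path to a TSV file.
#' @return a `data.frame` with columns `probe_id` (unique), `chrom`,
#'   `pos` (integer, >= 1) and `cpg_island` (logical).
#' @seealso [select_probes()], [read_methylation()]
#' @export
read_manifest <- function(path) {
  df <- read_table_checked(path, c("probe_id", "chrom", "pos", "cpg_island"),
                           sep = "\t")
  dup <- duplicated(df$probe_id)
  if (any(dup)) {
    stop_xci("duplicate probe_id in manifest: %s",
             paste(unique(df$probe_id[dup]), collapse = ", "))
  }
  pos <- suppressWarnings(as.integer(df$pos))
  bad <- is.na(pos) | pos < 1
  if (any(bad)) {
    stop_xci("manifest line %d: position must be an integer >= 1 (got '%s')",
             which(bad)[1] + 1L, df$pos[which(bad)[1]])
  }
  isl <- parse_logical(df$cpg_island)
  if (anyNA(isl)) {
    stop_xci("manifest line %d: cpg_island must be true/false (got '%s')",
             which(is.na(isl))[1] + 1L, df$cpg_island[which(is.na(isl))[1]])
  }
  data.frame(probe_id = df$probe_id,
             chrom = normalize_chromosome(df$chrom),
             pos = pos, cpg_island = isl, stringsAsFactors = FALSE)
}

#' Read a beta-value methylation matrix
#'
#' Tab-separated matrix: first column `probe_id`, one column per sample.
#' Empty cells are missing values; any non-missing beta outside \[0, 1\]
#' is rejected with the offending probe and sample named. Probes absent
#' from the manifest are dropped (count logged), so the returned matrix is
#' always annotated.
#'
#' @param path path to a TSV file.
#' @param manifest manifest `data.frame` from [read_manifest()].
#' @return numeric matrix (probes x samples) with `dimnames`, entries in
#'   \[0, 1\] or `NA`.
#' @export
read_methylation <- function(path, manifest) {
  m <- read_matrix_tsv(path, "probe_id")
  bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop_xci("beta value out of [0,1]: probe '%s', sample '%s' (value %s)",
             rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]],
             format(m[bad[1, , drop = FALSE]]))
  }
  keep <- rownames(m) %in% manifest$probe_id
  if (any(!keep)) {
    xci_log("dropped %d methylation probe(s) absent from manifest", sum(!keep))
  }
  m <- m[keep, , drop = FALSE]
  if (nrow(m) == 0) stop_xci("no methylation probes remain after manifest restriction")
  m
}

#' Read segmented copy number (SEG format)
#'
#' Tab-separated IGV/Firehose SEG dialect with columns `Sample`,
#' `Chromosome`, `Start`, `End`, optionally `Num_Probes`, and
#' `Segment_Mean` (log2 tumor/normal ratio). Chromosome names are
#' canonicalized (`"23"` -> `"chrX"`). Segments must satisfy start < end
#' and be non-overlapping within each sample and chromosome.
#'
#' @param path path to a SEG file.
#' @return `data.frame` with columns `sample_id`, `chrom`, `start`, `end`,
#'   `seg_mean`.
#' @export
read_seg <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  names(raw) <- tolower(names(raw))
  need <- c("sample", "chromosome", "start", "end", "segment_mean")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    stop_xci("SEG file %s missing column(s): %s", path, paste(miss, collapse = ", "))
  }
  seg <- data.frame(sample_id = as.character(raw$sample),
                    chrom = normalize_chromosome(raw$chromosome),
                    start = as.numeric(raw$start),
                    end = as.numeric(raw$end),
                    seg_mean = as.numeric(raw$segment_mean),
                    stringsAsFactors = FALSE)
  validate_seg(seg)
}

validate_seg <- function(seg) {
  if (any(!is.finite(seg$seg_mean))) stop_xci("non-finite seg_mean in SEG data")
  bad <- seg$start >= seg$end
  if (any(bad)) {
    stop_xci("SEG segment with start >= end (sample '%s', %s:%s-%s)",
             seg$sample_id[bad][1], seg$chrom[bad][1],
             seg$start[bad][1], seg$end[bad][1])
  }
  for (key in unique(paste(seg$sample_id, seg$chrom))) {
    s <- seg[paste(seg$sample_id, seg$chrom) == key, , drop = FALSE]
    if (nrow(s) < 2) next
    s <- s[order(s$start), , drop = FALSE]
    if (any(s$start[-1] < s$end[-nrow(s)])) {
      stop_xci("overlapping SEG segments for sample '%s' on %s",
               s$sample_id[1], s$chrom[1])
    }
  }
  seg
}

#' Read a normalized RSEM expression matrix
#'
#' Tab-separated matrix: first column `gene_id`, one column per sample.
#' Empty cells are missing; negative values are rejected.
#'
#' @param path path to a TSV file.
#' @return numeric matrix (genes x samples), entries >= 0 or `NA`.
#' @export
read_expression <- function(path) {
  m <- read_matrix_tsv(path, "gene_id")
  bad <- which(!is.na(m) & m < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop_xci("negative RSEM value: gene '%s', sample '%s'",
             rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]])
  }
  m
}

#' Read a clinical covariate and outcome table
#'
#' Comma-separated with header `sample_id, histology, tcga_subtype, age,
#' stage, menopause, race, ethnicity, residual, os_time, os_event,
#' dfs_time, dfs_event`. Empty cells are missing; `histology` may not be
#' missing. Times are days and must be >= 0; events are 0/1.
#'
#' @param path path to a CSV file.
#' @return validated `data.frame`, one row per sample.
#' @export
read_clinical <- function(path) {
  need <- c("sample_id", "histology", "tcga_subtype", "age", "stage",
            "menopause", "race", "ethnicity", "residual",
            "os_time", "os_event", "dfs_time", "dfs_event")
  df <- read_table_checked(path, need, sep = ",")
  validate_clinical(df)
}

validate_clinical <- function(df) {
  assert_that(!anyDuplicated(df$sample_id), "duplicate sample_id in clinical table")
  out <- data.frame(sample_id = as.character(df$sample_id),
                    stringsAsFactors = FALSE)
  hist <- as_enum(df$histology, HISTOLOGIES, "histology")
  if (anyNA(hist)) stop_xci("histology missing for sample '%s'",
                            df$sample_id[which(is.na(hist))[1]])
  out$histology <- hist
  out$tcga_subtype <- as_enum(df$tcga_subtype, TCGA_SUBTYPES, "tcga_subtype")
  out$age <- num_or_na(df$age)
  out$stage <- as_enum(df$stage, STAGES, "stage")
  out$menopause <- as_enum(df$menopause, MENOPAUSE, "menopause")
  out$race <- blank_to_na(df$race)
  out$ethnicity <- blank_to_na(df$ethnicity)
  out$residual <- blank_to_na(df$residual)
  for (tm in c("os_time", "dfs_time")) {
    v <- num_or_na(df[[tm]])
    if (any(!is.na(v) & v < 0)) {
      stop_xci("%s must be >= 0 (sample '%s')", tm,
               df$sample_id[which(!is.na(v) & v < 0)[1]])
    }
    out[[tm]] <- v
  }
  for (ev in c("os_event", "dfs_event")) {
    v <- parse_logical(df[[ev]])
    bad <- is.na(v) & !is.na(blank_to_na(df[[ev]]))
    if (any(bad)) stop_xci("%s must be 0/1 (sample '%s')", ev, df$sample_id[bad][1])
    out[[ev]] <- v
  }
  out
}

#' Read a cancer-testis-antigen gene panel
#'
#' Plain-text file with one gene symbol per line; blank lines and lines
#' starting with `#` are ignored. The panel name defaults to the file
#' name without extension.
#'
#' @param path path to the gene list.
#' @param location `"X_linked"` or `"autosomal"`.
#' @param name panel name; defaults to the base file name.
#' @return list with elements `name`, `genes` (unique character vector)
#'   and `location`.
#' @export
read_panel <- function(path, location = c("X_linked", "autosomal"),
                       name = NULL) {
  location <- match.arg(location)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  genes <- unique(lines[nzchar(lines) & !startsWith(lines, "#")])
  if (length(genes) == 0) stop_xci("panel file %s contains no genes", path)
  list(name = if (is.null(name)) tools::file_path_sans_ext(basename(path)) else name,
       genes = genes, location = location)
}

CALL_COLUMNS <- c("sample_id", "histology", "cluster", "meth_class",
                  "xist_class", "p_arm_cnv", "q_arm_cnv", "p_arm_meth",
                  "q_arm_meth", "xci_group", "override_applied", "flags")

#' Write / read an XCI calls table
#'
#' One row per sample carrying the assigned group and its full evidence
#' trail (cluster id, methylation and XIST classes, per-arm copy-number
#' and methylation calls, override flag, conflict flags). `write_calls()`
#' followed by `read_calls()` is the identity on the table.
#'
#' @param calls calls `data.frame` (e.g. from [xci_classify()] via
#'   `as.data.frame()`).
#' @param path output TSV path.
#' @return `write_calls()` returns `path` invisibly; `read_calls()`
#'   returns the validated calls `data.frame`.
#' @export
write_calls <- function(calls, path) {
  calls <- as.data.frame(calls)
  miss <- setdiff(CALL_COLUMNS, names(calls))
  if (length(miss) > 0) stop_xci("calls table missing column(s): %s",
                                 paste(miss, collapse = ", "))
  out <- calls[, CALL_COLUMNS]
  out$override_applied <- tolower(as.character(out$override_applied))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calls
#' @export
read_calls <- function(path) {
  df <- read_table_checked(path, CALL_COLUMNS, sep = "\t")
  df$histology <- as_enum(df$histology, HISTOLOGIES, "histology")
  df$meth_class <- as_enum(df$meth_class, c("hyper", "partial", "hypo"), "meth_class")
  df$xist_class <- as_enum(df$xist_class, c("high", "low", "unknown"), "xist_class")
  for (cl in c("p_arm_cnv", "q_arm_cnv")) {
    df[[cl]] <- as_enum(df[[cl]], c("deleted", "neutral", "gained"), cl)
  }
  for (cl in c("p_arm_meth", "q_arm_meth")) {
    df[[cl]] <- as_enum(df[[cl]], c("hypo", "not_hypo", "no_probes"), cl)
  }
  df$xci_group <- as_enum(df$xci_group, XCI_GROUPS, "xci_group")
  df$override_applied <- parse_logical(df$override_applied)
  df$flags <- blank_to_na(df$flags)
  df$flags[is.na(df$flags)] <- ""
  df
}

# --- shared low-level parsing -------------------------------------------

read_table_checked <- function(path, need, sep) {
  if (!file.exists(path)) stop_xci("file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                          colClasses = "character", check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop_xci("file %s missing column(s): %s", path, paste(miss, collapse = ", "))
  }
  nf <- utils::count.fields(path, sep = sep, quote = "", comment.char = "")
  if (any(nf != nf[1])) {
    stop_xci("malformed row at line %d of %s (expected %d fields, got %d)",
             which(nf != nf[1])[1], path, nf[1], nf[nf != nf[1]][1])
  }
  df
}

# TSV matrix keyed by its first column; values numeric, empty = NA.
read_matrix_tsv <- function(path, key) {
  if (!file.exists(path)) stop_xci("file not found: %s", path)
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE)
  if (names(df)[1] != key) {
    stop_xci("file %s: first column must be '%s' (got '%s')", path, key, names(df)[1])
  }
  ids <- df[[1]]
  if (anyDuplicated(ids)) stop_xci("duplicate %s in %s: %s", key, path,
                                   ids[duplicated(ids)][1])
  if (anyDuplicated(names(df)[-1])) stop_xci("duplicate sample columns in %s", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  m[!nzchar(m)] <- NA_character_
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Write a numeric matrix as the package's TSV dialect
#' @param m numeric matrix with dimnames.
#' @param path output path.
#' @param key name for the id column (`"probe_id"` or `"gene_id"`).
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path, key = "probe_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- key
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

parse_logical <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "1", "yes")] <- TRUE
  out[x %in% c("false", "f", "0", "no")] <- FALSE
  out
}

blank_to_na <- function(x) {
  x <- as.character(x)
  x[!nzchar(x)] <- NA_character_
  x
}

num_or_na <- function(x) {
  x <- blank_to_na(x)
  out <- suppressWarnings(as.numeric(x))
  if (any(is.na(out) & !is.na(x))) {
    stop_xci("non-numeric value where number expected: '%s'", x[is.na(out) & !is.na(x)][1])
  }
  out
}
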