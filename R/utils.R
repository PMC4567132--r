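# Internal helpers shared across the package.

XCI_GROUPS <- c("preserved_Xi", "Xa_plus", "two_Xa")
HISTOLOGIES <- c("endometrioid", "serous")
TCGA_SUBTYPES <- c("CN_high", "CN_low", "MSI", "POLE")
STAGES <- c("I_II", "III", "IV")
MENOPAUSE <- c("post", "pre", "peri")
CHROMOSOMES <- c(paste0("chr", 1:22), "chrX")

xci_log <- function(...) {
  if (!isTRUE(getOption("xciscope.quiet", FALSE))) {
    message("[xciscope] ", sprintf(...))
  }
  invisible(NULL)
}

stop_xci <- function(...) stop(sprintf(...), call. = FALSE)

#' @keywords internal
assert_that <- function(cond, ...) {
  if (!isTRUE(cond)) stop_xci(...)
  invisible(TRUE)
}

# "23"/"X"/"chr23" -> "chrX"; "1"/"chr1" -> "chr1". Errors on anything else.
normalize_chromosome <- function(chrom) {
  x <- sub("^chr", "", as.character(chrom))
  x[x %in% c("23", "X", "x")] <- "X"
  out <- paste0("chr", x)
  bad <- !(out %in% CHROMOSOMES)
  if (any(bad)) {
    stop_xci("unknown chromosome(s): %s (allowed: chr1..chr22, chrX)",
             paste(unique(chrom[bad]), collapse = ", "))
  }
  out
}

# log2(RSEM + 1), the expression transform used throughout.
log2p1 <- function(x) log2(x + 1)

# factor with fixed, validated levels; empty strings/NA -> NA
as_enum <- function(x, levels, field) {
  x <- as.character(x)
  x[!nzchar(x) | is.na(x)] <- NA_character_
  bad <- !is.na(x) & !(x %in% levels)
  if (any(bad)) {
    stop_xci("field '%s' has unknown level(s): %s (allowed: %s)", field,
             paste(unique(x[bad]), collapse = ", "),
             paste(levels, collapse = ", "))
  }
  factor(x, levels = levels)
}
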