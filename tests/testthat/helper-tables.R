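# Published cross-tabulations used as worked-example inputs.

histology_xci_counts <- function() {
  matrix(c(232, 49,
           19, 33,
           25, 13), nrow = 3, byrow = TRUE,
         dimnames = list(c("preserved_Xi", "Xa_plus", "two_Xa"),
                         c("endometrioid", "serous")))
}

ethnicity_xci_counts <- function() {
  matrix(c(5, 2, 2,
           205, 36, 29), nrow = 2, byrow = TRUE,
         dimnames = list(c("hispanic", "not_hispanic"),
                         c("preserved_Xi", "Xa_plus", "two_Xa")))
}

race_xci_counts <- function() {
  matrix(c(208, 35, 28,
           44, 11, 8,
           14, 2, 0), nrow = 3, byrow = TRUE,
         dimnames = list(c("white", "black", "asian"),
                         c("preserved_Xi", "Xa_plus", "two_Xa")))
}

stage_xci_counts <- function() {
  matrix(c(209, 34, 24,
           57, 15, 10,
           15, 2, 4), nrow = 3, byrow = TRUE,
         dimnames = list(c("I_II", "III", "IV"),
                         c("preserved_Xi", "Xa_plus", "two_Xa")))
}

# expand a counts matrix back into the pair of label vectors it tabulates
labels_from_counts <- function(counts) {
  rows <- rep(rownames(counts)[row(counts)], counts)
  cols <- rep(colnames(counts)[col(counts)], counts)
  list(rows = rows, cols = cols)
}
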