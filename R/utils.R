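# Internal constants and helpers shared across stages.

# the 20 standard amino acids, Biostrings ordering
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

PAD_CHAR <- "_"

STY <- c("S", "T", "Y")

# round-half-up, so 0.5 always goes up (base round() is round-half-even)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

pf_log <- function(stage, fmt, ...) {
  message(sprintf("INFO [%s] %s", stage, sprintf(fmt, ...)))
}

site_id <- function(protein_id, position, residue) {
  paste0(protein_id, "_", position, residue)
}

# split length-13 windows into an n x 13 character matrix
window_matrix <- function(windows) {
  n <- length(windows)
  if (n == 0L) {
    return(matrix(character(0), nrow = 0, ncol = 13))
  }
  stopifnot(all(nchar(windows) == 13L))
  matrix(unlist(strsplit(windows, "", fixed = TRUE), use.names = FALSE),
         nrow = n, ncol = 13L, byrow = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_pf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
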