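# Internal numeric and sequence helpers shared across modules.

#' @importFrom stats rbinom runif setNames
#' @importFrom utils read.delim write.table
NULL

# log(sum(exp(x))) without overflow/underflow; x may contain -Inf
logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

# one-letter -> three-letter amino-acid codes (HGVS style)
AA3 <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
  E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
  M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
  Y = "Tyr", V = "Val", `*` = "Ter"
)

aa3 <- function(aa1) {
  out <- AA3[strsplit(aa1, "")[[1]]]
  if (anyNA(out)) stop("unknown amino-acid code in ", aa1)
  paste0(out, collapse = "")
}

# Translate a DNA string (character) in frame 0 with the standard code.
# Returns list(protein, stopped, stop_codon_index): protein excludes the
# stop; stop_codon_index is the 1-based codon position of the terminator
# (NA when translation runs off the end of the sequence).
translate_to_stop <- function(dna) {
  dna <- toupper(dna)
  n_codons <- nchar(dna) %/% 3L
  if (n_codons == 0L) {
    return(list(protein = "", stopped = FALSE, stop_codon_index = NA_integer_))
  }
  starts <- seq.int(1L, by = 3L, length.out = n_codons)
  codons <- substring(dna, starts, starts + 2L)
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  stop_at <- which(aa == "*")
  if (length(stop_at) > 0L) {
    k <- stop_at[1L]
    list(protein = paste0(aa[seq_len(k - 1L)], collapse = ""),
         stopped = TRUE, stop_codon_index = as.integer(k))
  } else {
    list(protein = paste0(aa, collapse = ""),
         stopped = FALSE, stop_codon_index = NA_integer_)
  }
}

revcomp <- function(dna) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
}

# Deterministic RNG scope: evaluate expr with a temporary seed, restoring
# the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
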