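# Internal sequence and RNG helpers.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement a character vector of DNA sequences
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()] that keeps
#' plain character vectors in and out, as the rest of the package works with
#' tag sequences stored in tibble columns.
#'
#' @param x Character vector of DNA sequences (A/C/G/T, T==U).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Normalise to uppercase DNA alphabet (U -> T); error on anything else
# unless N is allowed.
normalize_seq <- function(x, allow_n = FALSE) {
  x <- toupper(x)
  x <- gsub("U", "T", x, fixed = TRUE)
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- !grepl(pat, x)
  if (any(bad)) {
    stop("non-nucleotide characters in sequence(s): ",
         paste(utils::head(x[bad], 3), collapse = ", "), call. = FALSE)
  }
  x
}

# Deterministic per-operation substream: derives a 32-bit seed from the root
# seed and a stream label so that each generator stage has its own
# reproducible stream regardless of how many draws earlier stages made.
substream_seed <- function(root_seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)) * 131L)
  as.integer((as.double(root_seed) * 48271 + h) %% 2147483647)
}

with_substream <- function(root_seed, label, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(substream_seed(root_seed, label))
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  force(code)
}

# Random DNA sequences of the given lengths, drawn in one vectorised pass.
random_dna <- function(lengths, bases = DNA_BASES, prob = NULL) {
  total <- sum(lengths)
  if (total == 0) return(rep("", length(lengths)))
  chars <- sample(bases, total, replace = TRUE, prob = prob)
  ends <- cumsum(lengths)
  starts <- ends - lengths + 1
  big <- paste(chars, collapse = "")
  substring(big, starts, ends)
}

# Apply per-base substitution errors at rate `rate` to a character vector of
# sequences; substitutions are uniform over the three other bases.
mutate_seqs <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0) return(seqs)
  lens <- nchar(seqs)
  n_mut <- stats::rbinom(length(seqs), lens, rate)
  idx <- which(n_mut > 0)
  for (i in idx) {
    pos <- sample.int(lens[i], n_mut[i])
    s <- strsplit(seqs[i], "")[[1]]
    for (p in pos) {
      s[p] <- sample(setdiff(DNA_BASES, s[p]), 1)
    }
    seqs[i] <- paste(s, collapse = "")
  }
  seqs
}

round2 <- function(x) round(x, 2)

`%||%` <- function(a, b) if (is.null(a)) b else a
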