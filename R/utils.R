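# Shared helpers: seeded RNG scoping, sequence utilities, FASTA/FASTQ IO.

DNA_BASES <- c("A", "C", "G", "T")
AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' caller's RNG state, so seeded operations do not perturb each other.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# deterministic sub-seed derivation, kept below 2^31
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 1000003L) * 1009 + k * 97 + 1) %% 2147483647L
}

#' Reverse-complement nucleotide strings
#'
#' @param x Character vector of A/C/G/T/N strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

# hamming mismatches between equal-length strings (byte compare)
str_mismatches <- function(a, b) {
  sum(charToRaw(a) != charToRaw(b))
}

phred_to_int <- function(qual) {
  lapply(qual, function(q) utf8ToInt(q) - 33L)
}

int_to_phred <- function(q) {
  vapply(q, function(v) intToUtf8(v + 33L), character(1))
}

# ---------------------------------------------------------------------------
# IO: reads are plain data.frames with columns id, seq, qual (Phred+33)
# ---------------------------------------------------------------------------

#' Read a FASTQ file into a reads table
#'
#' @param path FASTQ file (Phred+33).
#' @return A data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(id = names(x), seq = as.character(x),
             qual = as.character(S4Vectors::mcols(x)$qualities),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a reads table to FASTQ (Phred+33)
#'
#' @param reads data.frame with columns `id`, `seq`, `qual`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

#' Read FASTA sequences, keeping description-line key=value fields
#'
#' Description fields of the form `key=value` (for example
#' `topology=circular`) are parsed into columns.
#'
#' @param path FASTA file.
#' @return data.frame with columns `id`, `seq` plus one column per key.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  parse_desc_table(names(x), as.character(x))
}

#' Read protein FASTA, keeping description-line key=value fields
#'
#' @param path FASTA file of amino-acid sequences.
#' @return data.frame with columns `id`, `seq` plus one column per key.
#' @export
read_protein_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  parse_desc_table(names(x), as.character(x))
}

parse_desc_table <- function(headers, seqs) {
  ids <- sub("\\s.*$", "", headers)
  out <- data.frame(id = ids, seq = unname(seqs), row.names = NULL,
                    stringsAsFactors = FALSE)
  kv <- regmatches(headers, gregexpr("[A-Za-z_]+=[^ ]+", headers))
  keys <- unique(unlist(lapply(kv, function(p) sub("=.*$", "", p))))
  for (k in keys) {
    out[[k]] <- vapply(kv, function(p) {
      hit <- grep(paste0("^", k, "="), p, value = TRUE)
      if (length(hit)) sub("^[^=]+=", "", hit[1]) else NA_character_
    }, character(1))
  }
  out
}

#' Write sequences to FASTA with key=value description fields
#'
#' @param seqs Named character vector (or data.frame with `id`, `seq`).
#' @param path Output path.
#' @param desc Optional character vector of description strings.
#' @param protein Write as amino acids rather than DNA.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, desc = NULL, protein = FALSE) {
  if (is.data.frame(seqs)) {
    ids <- seqs$id
    ss <- seqs$seq
  } else {
    ids <- names(seqs)
    ss <- unname(seqs)
  }
  hdr <- if (is.null(desc)) ids else paste(ids, desc)
  x <- if (protein) Biostrings::AAStringSet(ss) else Biostrings::DNAStringSet(ss)
  names(x) <- hdr
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
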