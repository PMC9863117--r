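# Amino-acid set specifications and composition-weighted random sequences.

#' Define an amino-acid set
#'
#' An amino-acid set is a named alphabet with positive relative residue
#' frequencies. Weights need not sum to one; sampling normalizes them.
#'
#' @param name Label for the set (e.g. `"GADV"`).
#' @param frequencies Named numeric vector of positive relative weights;
#'   names are one-letter residue symbols drawn from G, A, D, V, E, L.
#' @return An object of class `aa_set`.
#' @examples
#' amino_acid_set("GADV", c(G = 1, A = 1, D = 1, V = 1))
#' @export
amino_acid_set <- function(name, frequencies) {
  if (!length(frequencies)) stop("frequencies: at least one residue required")
  if (is.null(names(frequencies)) || any(!nzchar(names(frequencies))))
    stop("frequencies must be a named vector of residue symbols")
  syms <- names(frequencies)
  bad <- setdiff(syms, names(AA3))
  if (length(bad))
    stop("frequencies: unsupported residue symbol(s): ",
         paste(bad, collapse = ", "))
  if (any(!is.finite(frequencies)) || any(frequencies <= 0))
    stop("frequencies: all weights must be positive and finite")
  structure(list(name = name, frequencies = frequencies), class = "aa_set")
}

#' @export
print.aa_set <- function(x, ...) {
  p <- x$frequencies / sum(x$frequencies)
  cat(sprintf("<amino-acid set> %s: %s\n", x$name,
              paste(sprintf("%s=%.3g", names(p), p), collapse = " ")))
  invisible(x)
}

#' Normalized residue probabilities of a set
#' @param set An `aa_set`.
#' @export
set_probabilities <- function(set) {
  stopifnot(inherits(set, "aa_set"))
  set$frequencies / sum(set$frequencies)
}

#' The five built-in amino-acid sets
#'
#' The primitive GADV alphabet and its studied extensions:
#' * `GADV` — G:A:D:V = 1:1:1:1
#' * `GADVA` — alanine doubled, G:A:D:V = 1:2:1:1
#' * `GADVE` — glutamate added, 1:1:1:1:1
#' * `GADVL` — leucine added, 1:1:1:1:1
#' * `GA(D/E)V` — G:A:D:V:E = 2:2:1:2:1, the occurrence ratio of the
#'   GNN codon block in which D and E appear at half the rate of G, A, V
#'
#' @return A named list of `aa_set` objects.
#' @export
builtin_sets <- function() {
  list(
    "GADV" = amino_acid_set("GADV", c(G = 1, A = 1, D = 1, V = 1)),
    "GADVA" = amino_acid_set("GADVA", c(G = 1, A = 2, D = 1, V = 1)),
    "GADVE" = amino_acid_set("GADVE", c(G = 1, A = 1, D = 1, V = 1, E = 1)),
    "GADVL" = amino_acid_set("GADVL", c(G = 1, A = 1, D = 1, V = 1, L = 1)),
    "GA(D/E)V" = amino_acid_set("GA(D/E)V",
                                c(G = 2, A = 2, D = 1, V = 2, E = 1))
  )
}

#' Fetch one built-in set by name
#' @param name One of `"GADV"`, `"GADVA"`, `"GADVE"`, `"GADVL"`,
#'   `"GA(D/E)V"`.
#' @export
builtin_set <- function(name) {
  sets <- builtin_sets()
  if (!name %in% names(sets))
    stop("unknown built-in set: ", name, " (available: ",
         paste(names(sets), collapse = ", "), ")")
  sets[[name]]
}

# Deterministic per-sequence substream seed so that increasing n leaves the
# first sequences unchanged. Kept below 2^31.
substream_seed <- function(master, k) {
  as.integer((as.double(master) %% 59999L) * 31013 + 7919 * k) %% 2147483647L
}

#' Generate random peptide sequences from an amino-acid set
#'
#' Residues are drawn independently at each position with probability
#' proportional to the set weights; each sequence uses its own RNG substream
#' derived from `seed`, so identical `(set, length, seed)` reproduce the same
#' leading sequences for any `n`.
#'
#' @param set An `aa_set`.
#' @param n Number of peptides.
#' @param length Residues per peptide (the study default is 20).
#' @param seed Integer master seed.
#' @return A data frame with columns `id`, `set`, `sequence`.
#' @examples
#' head(generate_sequences(builtin_set("GADV"), n = 5, length = 20, seed = 1))
#' @export
generate_sequences <- function(set, n, length, seed = 1L) {
  stopifnot(inherits(set, "aa_set"))
  if (!is.numeric(n) || n < 1) stop("n must be a positive count")
  if (!is.numeric(length) || length < 1) stop("length must be a positive count")
  n <- as.integer(n); length <- as.integer(length)
  p <- set_probabilities(set)
  syms <- names(p)
  seqs <- character(n)
  for (k in seq_len(n)) {
    withr_seed <- substream_seed(seed, k)
    old <- .Random.seed_exists()
    set.seed(withr_seed)
    seqs[k] <- paste(sample(syms, length, replace = TRUE, prob = p),
                     collapse = "")
    restore_rng(old)
  }
  safe <- gsub("[^A-Za-z0-9]", "", set$name)
  data.frame(id = sprintf("%s_%03d", safe, seq_len(n)),
             set = set$name, sequence = seqs, stringsAsFactors = FALSE)
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' Write peptide sequences to FASTA
#'
#' One record per peptide; the description line carries the id and the set
#' name (`>GADV_001 set=GADV`).
#'
#' @param sequences Data frame from [generate_sequences()].
#' @param path Output file.
#' @export
write_fasta <- function(sequences, path) {
  ids <- sprintf("%s set=%s", sequences$id, sequences$set)
  bio3d::write.fasta(seqs = do.call(rbind, strsplit(sequences$sequence, "")),
                     ids = ids, file = path)
  invisible(path)
}

#' Read peptide sequences from FASTA
#' @param path FASTA file written by [write_fasta()] (or any standard FASTA).
#' @return A data frame with columns `id`, `set`, `sequence`.
#' @export
read_fasta <- function(path) {
  fa <- bio3d::read.fasta(path)
  ids <- rownames(fa$ali)
  seqs <- apply(fa$ali, 1, function(r) paste(r[r != "-"], collapse = ""))
  id <- sub("\\s.*$", "", ids)
  set <- ifelse(grepl("set=", ids), sub(".*set=(\\S+).*", "\\1", ids), NA)
  data.frame(id = id, set = set, sequence = unname(seqs),
             stringsAsFactors = FALSE)
}
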