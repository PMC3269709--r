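#' Construct a nucleotide sequence record
#'
#' The basic container used throughout the package: an id, an uppercase
#' sequence string and a DNA/RNA alphabet flag. Lowercase input is
#' normalised to uppercase; the alphabet is inferred from the characters
#' when not given (presence of U implies RNA, T implies DNA; a sequence
#' with both is rejected).
#'
#' @param seq Nucleotide string (characters ACGT or ACGU, any case).
#' @param id Identifier label (default `"seq1"`).
#' @param alphabet `"DNA"`, `"RNA"`, or `NULL` to infer. Sequences without
#'   T or U (e.g. `"ACG"`) default to DNA unless specified.
#' @return An object of class `nuc_seq`: a list with elements `id`, `seq`,
#'   `alphabet`.
#' @examples
#' nuc_seq("ucagucuuuuucu", id = "mir-14-5p")
#' @export
nuc_seq <- function(seq, id = "seq1", alphabet = NULL) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || !nzchar(seq))
    stop("'seq' must be a non-empty character scalar", call. = FALSE)
  s <- toupper(seq)
  bad <- gsub("[ACGTU]", "", s)
  if (nzchar(bad))
    stop(sprintf("invalid character(s) '%s' in sequence '%s'",
                 paste(unique(strsplit(bad, "")[[1]]), collapse = ""), id),
         call. = FALSE)
  has_t <- grepl("T", s, fixed = TRUE)
  has_u <- grepl("U", s, fixed = TRUE)
  if (has_t && has_u)
    stop(sprintf("sequence '%s' mixes T and U", id), call. = FALSE)
  inferred <- if (has_u) "RNA" else if (has_t) "DNA" else NULL
  if (is.null(alphabet)) alphabet <- if (is.null(inferred)) "DNA" else inferred
  alphabet <- match.arg(alphabet, c("DNA", "RNA"))
  if (!is.null(inferred) && inferred != alphabet)
    stop(sprintf("sequence '%s' is not valid %s", id, alphabet), call. = FALSE)
  structure(list(id = as.character(id), seq = s, alphabet = alphabet),
            class = "nuc_seq")
}

#' @export
print.nuc_seq <- function(x, ...) {
  cat(sprintf("<nuc_seq> %s [%s, %d nt]\n  %s\n",
              x$id, x$alphabet, nchar(x$seq), x$seq))
  invisible(x)
}

#' @export
as.character.nuc_seq <- function(x, ...) x$seq

#' @rdname nuc_seq
#' @param x Object to test.
#' @export
is_nuc_seq <- function(x) inherits(x, "nuc_seq")

# Coerce character input to nuc_seq, pass nuc_seq through.
as_nuc_seq <- function(x, id = "seq1", alphabet = NULL) {
  if (is_nuc_seq(x)) x else nuc_seq(x, id = id, alphabet = alphabet)
}

#' Reverse complement
#'
#' Complements and reverses a sequence within its own alphabet (A-T/G-C for
#' DNA, A-U/G-C for RNA). `revcomp(revcomp(x))` is the identity.
#'
#' @param x A [nuc_seq] or a plain character string (alphabet inferred).
#' @return Same type as the input; for a `nuc_seq` the id gains a `_rc`
#'   suffix.
#' @examples
#' revcomp("TAGGAG")  # "CTCCTA"
#' @export
revcomp <- function(x) {
  if (is_nuc_seq(x)) {
    xs <- if (x$alphabet == "RNA") Biostrings::RNAString(x$seq)
          else Biostrings::DNAString(x$seq)
    nuc_seq(as.character(Biostrings::reverseComplement(xs)),
            id = paste0(x$id, "_rc"), alphabet = x$alphabet)
  } else {
    as.character(revcomp(as_nuc_seq(x)))
  }
}

#' Convert between RNA and DNA alphabets
#'
#' U/T substitution with the alphabet flag flipped; the two functions are
#' inverses. Character input is accepted and returns character.
#'
#' @param x A [nuc_seq] or character string.
#' @return Same type as the input.
#' @examples
#' rna_to_dna("UCAGUCUUUUUCU")  # "TCAGTCTTTTTCT"
#' @export
rna_to_dna <- function(x) {
  if (is_nuc_seq(x)) {
    if (x$alphabet == "DNA") return(x)
    nuc_seq(chartr("U", "T", x$seq), id = x$id, alphabet = "DNA")
  } else {
    s <- as_nuc_seq(x, alphabet = if (grepl("T", toupper(x))) "DNA" else "RNA")
    chartr("U", "T", toupper(s$seq))
  }
}

#' @rdname rna_to_dna
#' @export
dna_to_rna <- function(x) {
  if (is_nuc_seq(x)) {
    if (x$alphabet == "RNA") return(x)
    nuc_seq(chartr("T", "U", x$seq), id = x$id, alphabet = "RNA")
  } else {
    s <- as_nuc_seq(x, alphabet = if (grepl("U", toupper(x))) "RNA" else "DNA")
    chartr("T", "U", toupper(s$seq))
  }
}

#' Read and write FASTA files
#'
#' `read_fasta()` parses a (possibly line-wrapped) multi-record FASTA file
#' into a list of [nuc_seq] records; the id is the header token up to the
#' first whitespace (miRBase convention) and sequences are uppercased with
#' per-record alphabet inference. Duplicate ids, empty files and
#' non-nucleotide characters are errors naming the offending record.
#'
#' @param path File path.
#' @return `read_fasta()`: a named list of `nuc_seq`. `write_fasta()`:
#'   invisibly, `path`.
#' @export
read_fasta <- function(path) {
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop(sprintf(
                    "cannot parse FASTA '%s': %s", path, conditionMessage(e)),
                    call. = FALSE))
  if (length(set) == 0L)
    stop(sprintf("FASTA '%s' contains no records", path), call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop(sprintf("duplicate FASTA id(s): %s", paste(unique(dup), collapse = ", ")),
         call. = FALSE)
  recs <- lapply(seq_along(set), function(i) {
    tryCatch(nuc_seq(as.character(set[[i]]), id = ids[i]),
             error = function(e) stop(sprintf(
               "record '%s': %s", ids[i], conditionMessage(e)), call. = FALSE))
  })
  names(recs) <- ids
  recs
}

#' @rdname read_fasta
#' @param records A list of [nuc_seq] (a single `nuc_seq` is accepted).
#' @param width Line-wrap width for sequence lines.
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (is_nuc_seq(records)) records <- list(records)
  stopifnot(length(records) > 0L, all(vapply(records, is_nuc_seq, logical(1))))
  set <- Biostrings::BStringSet(vapply(records, function(r) r$seq, character(1)))
  names(set) <- vapply(records, function(r) r$id, character(1))
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Percent identity from global alignment
#'
#' Needleman-Wunsch global alignment of two same-alphabet sequences (via
#' [Biostrings::pairwiseAlignment()]) under a linear gap penalty, reporting
#' identity as matches / alignment columns (gap columns included in the
#' denominator) x 100, rounded to 0.1%.
#'
#' @param a,b [nuc_seq] records or character strings; both must be the same
#'   alphabet.
#' @param match,mismatch,gap Alignment scores (defaults +1 / 0 / -1). These
#'   are chosen for identity reporting, not biological realism.
#' @return Percent identity (0-100, one decimal place).
#' @examples
#' global_identity("ACGTACGT", "ACGTACGT")  # 100
#' @export
global_identity <- function(a, b, match = 1, mismatch = 0, gap = -1) {
  a <- as_nuc_seq(a, id = "a"); b <- as_nuc_seq(b, id = "b")
  if (a$alphabet != b$alphabet)
    stop("sequences must share an alphabet", call. = FALSE)
  if (gap > 0) stop("'gap' must be a penalty (<= 0)", call. = FALSE)
  sa <- chartr("U", "T", a$seq); sb <- chartr("U", "T", b$seq)
  bases <- c("A", "C", "G", "T")
  sub <- matrix(mismatch, 4, 4, dimnames = list(bases, bases))
  diag(sub) <- match
  aln <- Biostrings::pairwiseAlignment(
    sa, sb, type = "global", substitutionMatrix = sub,
    gapOpening = 0, gapExtension = -gap)
  p <- as.character(Biostrings::alignedPattern(aln))
  s <- as.character(Biostrings::alignedSubject(aln))
  cols <- nchar(p)
  matches <- sum(strsplit(p, "")[[1]] == strsplit(s, "")[[1]] &
                   strsplit(p, "")[[1]] != "-")
  round(100 * matches / cols, 1)
}
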