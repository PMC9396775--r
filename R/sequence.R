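#' AB sequences
#'
#' An `ab_sequence` is a chain over the two-letter alphabet \{A, B\}:
#' A marks hydrophobic residues (polarity +1), B hydrophilic (polarity -1).
#' It is stored as a character vector of single letters with class
#' `"ab_sequence"` and an optional `id` attribute carrying the FASTA header.
#'
#' @param x a single string such as `"ABBAB"`, or a character vector of
#'   single letters. Lowercase a/b are accepted and uppercased.
#' @param id optional record identifier (FASTA header text).
#' @return an `ab_sequence` object.
#' @examples
#' s <- ab_sequence("ABBAB")
#' length(s)
#' eta_of(s)
#' @export
ab_sequence <- function(x, id = NULL) {
  stopifnot(is.character(x), length(x) >= 1)
  letters_vec <- if (length(x) == 1L && nchar(x) > 1L)
    strsplit(x, "", fixed = TRUE)[[1]] else x
  letters_vec <- toupper(letters_vec)
  bad <- which(!(letters_vec %in% c("A", "B")))
  if (length(bad) > 0L) {
    stop(sprintf(
      "invalid residue letter(s) %s at position(s) %s: alphabet is {A, B}",
      paste(sQuote(letters_vec[bad[seq_len(min(3, length(bad)))]]),
            collapse = ", "),
      paste(bad[seq_len(min(3, length(bad)))], collapse = ", ")
    ), call. = FALSE)
  }
  structure(letters_vec, class = "ab_sequence", id = id)
}

#' @export
print.ab_sequence <- function(x, ...) {
  id <- attr(x, "id")
  cat(sprintf("<ab_sequence> n = %d%s\n  %s\n", length(x),
              if (is.null(id)) "" else paste0("  [", id, "]"),
              paste(unclass(x), collapse = "")))
  invisible(x)
}

#' @export
as.character.ab_sequence <- function(x, ...) paste(unclass(x), collapse = "")

as_ab_sequence <- function(x) {
  if (inherits(x, "ab_sequence")) x else ab_sequence(x)
}

#' Residue polarity vector
#'
#' Maps each residue to its polarity eta: +1 for hydrophobic A, -1 for
#' hydrophilic B. These are the eta_i entering the nonbonded pair coefficient.
#'
#' @param sequence an [ab_sequence()] or string coercible to one.
#' @return numeric vector of +1/-1, same length as the sequence.
#' @examples
#' eta_of("AB") # +1 -1
#' @export
eta_of <- function(sequence) {
  s <- as_ab_sequence(sequence)
  ifelse(unclass(s) == "A", 1, -1)
}

#' Fibonacci benchmark sequences
#'
#' The standard artificial benchmark family: S0 = "A", S1 = "B",
#' S_{i+1} = S_{i-1} concatenated with S_i. Lengths follow the Fibonacci
#' numbers, as do the A and B counts; the four classic test chains have
#' lengths 13, 21, 34 and 55 with compositions (5 A, 8 B), (8 A, 13 B),
#' (13 A, 21 B) and (21 A, 34 B).
#'
#' @param target_length requested chain length; must be a Fibonacci number.
#'   Length 1 is ambiguous (both seeds have length 1); S1 = "B" is returned.
#' @return an [ab_sequence()] with id `"fibonacci_<n>"`.
#' @examples
#' as.character(fibonacci_sequence(13))
#' @export
fibonacci_sequence <- function(target_length) {
  stopifnot(is.numeric(target_length), length(target_length) == 1L,
            target_length >= 1, target_length == round(target_length))
  target_length <- as.integer(target_length)
  prev <- "A"; cur <- "B"
  if (target_length == 1L)
    return(ab_sequence(cur, id = "fibonacci_1"))
  while (nchar(cur) < target_length) {
    nxt <- paste0(prev, cur)
    prev <- cur; cur <- nxt
  }
  if (nchar(cur) != target_length) {
    lens <- c(1, 2, 3, 5, 8, 13, 21, 34, 55, 89)
    stop(sprintf(
      "target_length %d is not a Fibonacci number; valid lengths are %s, ...",
      target_length, paste(lens, collapse = ", ")), call. = FALSE)
  }
  ab_sequence(cur, id = sprintf("fibonacci_%d", target_length))
}

#' Read and write AB sequences as FASTA
#'
#' Plain FASTA with records over \{A, B, a, b\}; lowercase letters are
#' uppercased on read. Any other character is rejected with the record name
#' and offending position.
#'
#' @param path file path.
#' @param sequences a list of [ab_sequence()] objects (or one object).
#' @return `read_ab_fasta` returns a named list of `ab_sequence`;
#'   `write_ab_fasta` returns `path` invisibly.
#' @export
read_ab_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  out <- vector("list", length(set))
  nms <- names(set)
  for (k in seq_along(set)) {
    chars <- strsplit(toupper(as.character(set[[k]])), "", fixed = TRUE)[[1]]
    bad <- which(!(chars %in% c("A", "B")))
    if (length(bad) > 0L) {
      stop(sprintf(
        "record '%s': invalid character '%s' at position %d (alphabet {A,B,a,b})",
        nms[k], chars[bad[1]], bad[1]), call. = FALSE)
    }
    out[[k]] <- ab_sequence(chars, id = nms[k])
  }
  names(out) <- nms
  out
}

#' @rdname read_ab_fasta
#' @export
write_ab_fasta <- function(sequences, path) {
  if (inherits(sequences, "ab_sequence")) sequences <- list(sequences)
  strs <- vapply(sequences, function(s) as.character(as_ab_sequence(s)), "")
  ids <- vapply(seq_along(sequences), function(k) {
    id <- attr(sequences[[k]], "id")
    if (is.null(id)) id <- names(sequences)[k]
    if (is.null(id) || is.na(id) || !nzchar(id)) id <- sprintf("seq_%d", k)
    id
  }, "")
  set <- Biostrings::BStringSet(setNames(strs, ids))
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}
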