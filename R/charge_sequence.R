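#' Charge sequences of K/E polyampholytes
#'
#' A `charge_sequence` represents a polyampholyte as an ordered string over
#' the two-letter alphabet \{K, E\}: lysine (K) carries charge +1, glutamate
#' (E) carries charge -1. Charges are derived deterministically from the
#' residues; a charge-neutral sequence has equal numbers of K and E.
#'
#' @param residues character vector of single residues, or a single string,
#'   over \{K, E\} (case-insensitive).
#' @param name identifier for the sequence.
#' @return An object of class `charge_sequence` with elements `residues`
#'   (character vector), `charges` (integer vector of +1/-1), and `name`.
#'   A warning is raised for sequences that are not charge-neutral, since
#'   the model series studied here is neutral by construction; non-neutral
#'   sequences are still accepted.
#' @examples
#' s <- charge_sequence("KEKEKE", name = "alt6")
#' s$charges
#' @export
charge_sequence <- function(residues, name = "seq") {
  if (is.character(residues) && length(residues) == 1L && nchar(residues) > 1L) {
    residues <- strsplit(residues, "")[[1]]
  }
  residues <- toupper(as.character(residues))
  if (length(residues) < 1L) {
    stop("charge_sequence: sequence must contain at least one residue")
  }
  bad <- setdiff(unique(residues), c("K", "E"))
  if (length(bad) > 0L) {
    stop(
      "charge_sequence: residue(s) without a charge assignment: ",
      paste(bad, collapse = ", "),
      " (only K (+1) and E (-1) are supported)"
    )
  }
  charges <- ifelse(residues == "K", 1L, -1L)
  net <- sum(charges)
  if (net != 0L) {
    warning(sprintf("sequence '%s' is not charge-neutral (net charge %+d)", name, net))
  }
  structure(
    list(residues = residues, charges = charges, name = name),
    class = "charge_sequence"
  )
}

#' @export
print.charge_sequence <- function(x, ...) {
  cat(sprintf(
    "<charge_sequence> %s: %d residues, net charge %+d\n  %s\n",
    x$name, length(x$residues), sum(x$charges),
    paste(x$residues, collapse = "")
  ))
  invisible(x)
}

#' @export
length.charge_sequence <- function(x) length(x$residues)

as_charge_sequence <- function(x, name = "seq") {
  if (inherits(x, "charge_sequence")) return(x)
  charge_sequence(x, name = name)
}

#' Read charge sequences from FASTA or plain text
#'
#' FASTA files are parsed with \pkg{seqinr}; files without a `>` header are
#' read as one sequence per line (optionally `name<whitespace>sequence`,
#' the registry format used for the KE series).
#'
#' @param path file path.
#' @return Named list of [charge_sequence()] objects.
#' @export
read_charge_sequences <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) > 0L && startsWith(first, ">")) {
    recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                               forceDNAtolower = FALSE)
    seqs <- lapply(seq_along(recs), function(i) {
      charge_sequence(as.character(recs[[i]])[1], name = names(recs)[i])
    })
    names(seqs) <- names(recs)
    return(seqs)
  }
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  seqs <- lapply(seq_along(lines), function(i) {
    parts <- strsplit(lines[i], "\\s+")[[1]]
    if (length(parts) >= 2L) {
      charge_sequence(parts[2], name = parts[1])
    } else {
      charge_sequence(parts[1], name = sprintf("seq%d", i))
    }
  })
  names(seqs) <- vapply(seqs, function(s) s$name, character(1))
  seqs
}

#' Write charge sequences to a FASTA file
#'
#' @param seqs list of [charge_sequence()] objects (or strings).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_charge_fasta <- function(seqs, path) {
  seqs <- lapply(seqs, as_charge_sequence)
  seqinr::write.fasta(
    sequences = lapply(seqs, function(s) s$residues),
    names = vapply(seqs, function(s) s$name, character(1)),
    file.out = path
  )
  invisible(path)
}

#' The packaged synthetic KE sequence series
#'
#' Loads the seven synthetic stand-in sequences (KE1--KE7) shipped with the
#' package in `inst/extdata/ke_synthetic.fasta`. These are length-50,
#' charge-neutral K/E polyampholytes generated by [generate_sequence_series()]
#' to span increasing charge blockiness (increasing normalized patterning
#' score Omega); they are synthetic stand-ins constructed by the package,
#' not literal published sequences, and any user-supplied registry read with
#' [read_charge_sequences()] can be used in their place.
#'
#' @return Named list of seven [charge_sequence()] objects, `KE1` ... `KE7`.
#' @export
ke_sequences <- function() {
  path <- system.file("extdata", "ke_synthetic.fasta", package = "condmix")
  if (!nzchar(path)) stop("packaged KE registry not found")
  read_charge_sequences(path)
}
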