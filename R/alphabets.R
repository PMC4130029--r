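# Residue alphabets: the 20-letter amino-acid set, the 4-letter DNA set, and
# compressed (reduced) amino-acid alphabets that partition the 20 residues
# into classes of biochemically similar residues.

#' The 20 standard amino-acid one-letter codes
#' @export
AMINO_ACIDS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' The 4 DNA bases
#' @export
DNA_BASES <- c("A", "C", "G", "T")

# Built-in compressed alphabets. Each entry is the partition of the 20
# amino acids into disjoint classes, one string per class.
.COMPRESSED_ALPHABETS <- list(
  "se-b14"   = c("A", "C", "D", "EQ", "FY", "G", "H", "IV", "KR", "LM",
                 "N", "P", "ST", "W"),
  "se-b10"   = c("AST", "C", "DN", "EQ", "FY", "G", "HW", "ILMV", "KR", "P"),
  "se-v10"   = c("AST", "C", "DEN", "FY", "G", "H", "ILMV", "KQR", "P", "W"),
  "li-a10"   = c("AC", "DE", "FWY", "G", "HN", "IV", "KQR", "LM", "P", "ST"),
  "li-b10"   = c("AST", "C", "DEQ", "FWY", "G", "HN", "IV", "KR", "LM", "P"),
  "solis-d10" = c("AM", "C", "DNS", "EKQR", "F", "GP", "HT", "IV", "LY", "W"),
  "solis-g10" = c("AEFIKLMQRVW", "C", "D", "G", "H", "N", "P", "S", "T", "Y"),
  "murphy10" = c("A", "C", "DENQ", "FWY", "G", "H", "ILMV", "KR", "P", "ST"),
  "se-b8"    = c("AST", "C", "DHN", "EKQR", "FWY", "G", "ILMV", "P"),
  "se-b6"    = c("AST", "CP", "DEHKNQR", "FWY", "G", "ILMV"),
  "dayhoff6" = c("AGPST", "C", "DENQ", "FWY", "HKR", "ILMV")
)

#' Construct an alphabet from residue classes
#'
#' An alphabet is a partition of a base residue set into disjoint classes.
#' Residues in one class are treated as identical for k-mer counting; each
#' class is represented by its alphabetically first member.
#'
#' @param name Short identifier for the alphabet.
#' @param classes Character vector, one string of residue letters per class.
#' @param base Character vector of the base residue set the classes must
#'   partition. Defaults to the union of the classes.
#' @return An object of class `kmer_alphabet` with elements `name`,
#'   `classes` (list of character vectors), `representatives` (named
#'   character vector mapping residue to class representative), `base`,
#'   and `size` (number of classes).
#' @examples
#' ab <- alphabet_from_classes("toy", c("AG", "CT"))
#' ab$representatives[["G"]]  # "A"
#' @export
alphabet_from_classes <- function(name, classes, base = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.character(classes) || length(classes) == 0L || any(!nzchar(classes)))
    stop("'classes' must be a character vector of non-empty class strings")
  cls <- lapply(strsplit(toupper(classes), ""), function(x) sort(unique(x)))
  members <- unlist(cls)
  if (anyDuplicated(members))
    stop("alphabet '", name, "' classes are not disjoint: residue(s) ",
         paste(unique(members[duplicated(members)]), collapse = ", "),
         " appear in more than one class")
  if (is.null(base)) base <- sort(members)
  base <- sort(unique(toupper(base)))
  if (!setequal(members, base))
    stop("alphabet '", name, "' classes do not partition the base set; ",
         "missing: ", paste(setdiff(base, members), collapse = ", "))
  reps <- character(0)
  for (cl in cls) reps[cl] <- cl[1L]  # alphabetically first member
  structure(
    list(name = name, classes = cls, representatives = reps,
         base = base, size = length(cls)),
    class = "kmer_alphabet"
  )
}

#' Retrieve a built-in alphabet by name
#'
#' Available names are `"identity-protein"` (the 20 amino acids, each its
#' own class), `"identity-dna"` (A, C, G, T), and the compressed
#' amino-acid alphabets `"se-b14"`, `"se-b10"`, `"se-v10"`, `"li-a10"`,
#' `"li-b10"`, `"solis-d10"`, `"solis-g10"`, `"murphy10"`, `"se-b8"`,
#' `"se-b6"`, `"dayhoff6"`.
#'
#' @param name Alphabet identifier (case-insensitive).
#' @return A `kmer_alphabet` object.
#' @examples
#' get_alphabet("dayhoff6")$size       # 6
#' get_alphabet("se-v10")$representatives[["V"]]  # "I"
#' @export
get_alphabet <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  key <- tolower(name)
  if (key == "identity-protein")
    return(alphabet_from_classes("identity-protein", AMINO_ACIDS))
  if (key == "identity-dna")
    return(alphabet_from_classes("identity-dna", DNA_BASES))
  if (key %in% names(.COMPRESSED_ALPHABETS))
    return(alphabet_from_classes(key, .COMPRESSED_ALPHABETS[[key]],
                                 base = AMINO_ACIDS))
  stop("unknown alphabet '", name, "'; valid names: identity-protein, ",
       "identity-dna, ", paste(names(.COMPRESSED_ALPHABETS), collapse = ", "))
}

#' List the names of all built-in alphabets
#' @return Character vector of valid `get_alphabet()` names.
#' @export
list_alphabets <- function() {
  c("identity-protein", "identity-dna", names(.COMPRESSED_ALPHABETS))
}

#' Translate a sequence into class-representative space
#'
#' Uppercases the input, then replaces every residue belonging to the
#' alphabet by the representative of its class (the alphabetically first
#' class member). Symbols outside the alphabet's base set (ambiguity
#' codes, gaps, ...) pass through unchanged; they are excluded later, at
#' k-mer counting. Output length always equals input length.
#'
#' @param sequence A single residue string.
#' @param alphabet A `kmer_alphabet` object or alphabet name.
#' @return The translated residue string.
#' @examples
#' translate_seq("SAT", get_alphabet("se-v10"))  # "AAA"
#' @export
translate_seq <- function(sequence, alphabet) {
  alphabet <- as_alphabet(alphabet)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  s <- toupper(sequence)
  reps <- alphabet$representatives
  chartr(paste(names(reps), collapse = ""), paste(reps, collapse = ""), s)
}

#' Coerce a name or object to a `kmer_alphabet`
#' @param x A `kmer_alphabet` object or a built-in alphabet name.
#' @return A `kmer_alphabet` object.
#' @export
as_alphabet <- function(x) {
  if (inherits(x, "kmer_alphabet")) return(x)
  if (is.character(x) && length(x) == 1L) return(get_alphabet(x))
  stop("expected a kmer_alphabet object or an alphabet name")
}

#' Read user-defined alphabets from a plain-text config file
#'
#' Each non-blank, non-comment line has the form `NAME: CLASS,CLASS,...`,
#' e.g. `my6: AGPST, C, DENQ, FWY, HKR, ILMV`. Classes must partition the
#' 20-letter amino-acid set unless `base` is given.
#'
#' @param path Path to the config file.
#' @param base Base residue set each alphabet must partition (default the
#'   20 amino acids).
#' @return Named list of `kmer_alphabet` objects.
#' @export
read_alphabet_config <- function(path, base = AMINO_ACIDS) {
  if (!file.exists(path)) stop("alphabet config not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      stop("malformed alphabet config line (expected 'NAME: CLASS,...'): ", ln)
    nm <- trimws(parts[1])
    cls <- trimws(strsplit(parts[2], ",", fixed = TRUE)[[1]])
    out[[nm]] <- alphabet_from_classes(nm, cls, base = base)
  }
  out
}

#' @export
print.kmer_alphabet <- function(x, ...) {
  cat("Alphabet '", x$name, "': ", x$size, " classes over ",
      length(x$base), " residues\n", sep = "")
  cat("  ", paste(vapply(x$classes, paste, "", collapse = ""),
                  collapse = ", "), "\n", sep = "")
  invisible(x)
}
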