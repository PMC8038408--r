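#' @importFrom jsonlite toJSON fromJSON write_json read_json
NULL

.LABELS <- c("drug", "metabolite", "fluorophore", "natural_product", "other")

# Run expr with a temporarily seeded RNG, restoring the caller's stream.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  eval.parent(substitute(expr))
}

#' Canonicalize SMILES strings
#'
#' Validates each string with the package's strict SMILES grammar and then
#' asks Open Babel for its canonical form, so that every molecular graph
#' maps to exactly one string. Canonicalization is idempotent: applying it
#' to its own output returns the same string.
#'
#' @param smiles character vector of SMILES
#' @return character vector of canonical SMILES, same length
#' @examples
#' canonicalizeSmiles(c("OCC", "CCO"))   # both give the same string
#' @export
canonicalizeSmiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  if (any(!nzchar(smiles))) stop("empty SMILES string")
  for (s in smiles) .parseSmiles(s)     # strict validation, names offender
  raw <- ChemmineOB::convertFormat("SMI", "CAN",
                                   paste(smiles, collapse = "\n"))
  out <- strsplit(raw, "\n", fixed = TRUE)[[1]]
  out <- trimws(sub("\t.*$", "", out))
  out <- out[nzchar(out)]
  if (length(out) != length(smiles))
    stop("canonicalization failed for at least one of: ",
         paste(utils::head(smiles, 5), collapse = ", "))
  out
}

#' Enumerate alternative SMILES of a molecule
#'
#' Re-writes the molecule's SMILES starting from a uniformly random atom
#' and visiting neighbours in random order (enumeration augmentation).
#' Every returned string canonicalizes back to the same molecule.
#' Stereochemistry descriptors are refused because atom re-ordering would
#' silently change their meaning.
#'
#' @param smiles a single valid SMILES string
#' @param n number of independent draws
#' @param seed optional seed for a reproducible draw (caller RNG restored)
#' @return character vector of \code{n} SMILES strings
#' @examples
#' set.seed(1)
#' enumerateSmiles("CCO", n = 3)
#' @export
enumerateSmiles <- function(smiles, n = 1L, seed = NULL) {
  if (.hasStereo(smiles))
    stop("stereochemistry descriptors are not supported by enumeration: '",
         smiles, "'")
  g <- .parseSmiles(smiles)
  .withSeed(seed, {
    vapply(seq_len(n), function(i) {
      root <- if (length(g$tokens) > 1L)
        sample.int(length(g$tokens), 1L) else 1L
      .writeSmiles(g, root)
    }, character(1))
  })
}

#' Sample a contrastive positive pair
#'
#' Draws two independent enumerated SMILES of the same parent molecule, the
#' two augmented views a contrastive batch treats as a positive pair. Up to
#' \code{maxTries} redraws are made to obtain two distinct strings; for
#' small or highly symmetric molecules the two views may coincide.
#'
#' @param record a one-row data.frame (or list) with \code{id} and
#'   \code{smiles} fields, as produced by [moleculeRecords()]
#' @param maxTries redraw attempts before accepting a duplicate pair
#' @return list with \code{parent_id}, \code{x_i}, \code{x_j}
#' @export
samplePositivePair <- function(record, maxTries = 10L) {
  x_i <- enumerateSmiles(record$smiles)
  x_j <- enumerateSmiles(record$smiles)
  tries <- 0L
  while (identical(x_i, x_j) && tries < maxTries) {
    x_j <- enumerateSmiles(record$smiles)
    tries <- tries + 1L
  }
  list(parent_id = record$id, x_i = x_i, x_j = x_j)
}

#' Tokenize a SMILES string atomwise
#'
#' Two-letter organic-subset halogens (\code{Cl}, \code{Br}), bracket atoms
#' (\code{[...]} as a whole) and \code{\%nn} ring closures are single
#' tokens; every other character (atoms, bonds, ring digits, branches) is
#' its own token. Concatenating the tokens reproduces the input exactly.
#' Characters outside the SMILES alphabet become single-character tokens
#' and are reported with a message.
#'
#' @param smiles a single SMILES string
#' @return character vector of tokens
#' @examples
#' tokenizeSmiles("C(Cl)Br")   # "C" "(" "Cl" ")" "Br"
#' @export
tokenizeSmiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  if (!nzchar(smiles)) return(character(0))
  pat <- "\\[[^]]*\\]|Cl|Br|%[0-9]{2}|."
  toks <- regmatches(smiles, gregexpr(pat, smiles, perl = TRUE))[[1]]
  known <- "^(\\[[^]]*\\]|Cl|Br|%[0-9]{2}|[A-Za-z0-9]|[-=#$:/\\\\().+*])$"
  bad <- toks[!grepl(known, toks)]
  if (length(bad))
    message("tokenizeSmiles: unknown character token(s): ",
            paste(unique(bad), collapse = " "))
  toks
}

#' Build a token vocabulary from a corpus
#'
#' Collects every token occurring in the canonical SMILES of the corpus and
#' in \code{enumPasses} seeded enumeration passes over it (so that tokens
#' reachable only through augmentation are covered), then orders them:
#' the four specials first (pad=0, start=1, end=2, unk=3), chemical tokens
#' after in lexicographic byte order. Deterministic for a given corpus and
#' seed.
#'
#' @param records molecule records from [moleculeRecords()] (or a character
#'   vector of SMILES)
#' @param enumPasses number of enumeration passes used for token collection
#' @param seed seed of the collection passes
#' @return a [TokenVocabulary-class]
#' @export
buildVocabulary <- function(records, enumPasses = 10L, seed = 1L) {
  smiles <- if (is.character(records)) records else records$smiles
  if (length(smiles) == 0L) stop("empty corpus")
  toks <- unlist(lapply(smiles, tokenizeSmiles))
  if (enumPasses > 0L) {
    enum <- .withSeed(seed, unlist(lapply(smiles, function(s)
      enumerateSmiles(s, n = enumPasses))))
    toks <- c(toks, unlist(lapply(enum, tokenizeSmiles)))
  }
  chem <- sort(unique(toks), method = "radix")
  chem <- setdiff(chem, .SPECIALS)
  new("TokenVocabulary", tokens = c(.SPECIALS, chem))
}

#' Encode a SMILES string as a fixed-length id sequence
#'
#' Produces \code{<s> tokens </s> <pad>...} of total length \code{maxLen}
#' with 0-based token ids. Sequences that do not fit are an error (never
#' silently truncated).
#'
#' @param smiles a single SMILES string
#' @param vocab a [TokenVocabulary-class]
#' @param maxLen padded length (tokens + 2 must fit)
#' @param oov \code{"unk"} maps out-of-vocabulary tokens to the unknown id;
#'   \code{"error"} fails and lists the offenders
#' @return list with \code{tokenIds} (integer, length maxLen, 0-based),
#'   \code{trueLength} (tokens + start + end) and \code{padMask} (logical,
#'   TRUE at pad positions)
#' @export
encodeSequence <- function(smiles, vocab, maxLen, oov = c("unk", "error")) {
  oov <- match.arg(oov)
  toks <- tokenizeSmiles(smiles)
  tl <- length(toks) + 2L
  if (tl > maxLen)
    stop("SMILES '", smiles, "' needs ", tl,
         " positions but maxLen is ", maxLen)
  if (oov == "error") {
    miss <- setdiff(unique(toks), vocab@tokens)
    if (length(miss))
      stop("out-of-vocabulary token(s) in '", smiles, "': ",
           paste(miss, collapse = " "))
  }
  ids <- c(1L, tokenIndex(vocab, toks), 2L, rep(0L, maxLen - tl))
  list(tokenIds = ids, trueLength = tl,
       padMask = seq_len(maxLen) > tl)
}

#' Decode an id sequence back to a SMILES string
#'
#' Inverse of [encodeSequence()] for in-vocabulary tokens: special tokens
#' are dropped and the remaining tokens concatenated.
#'
#' @param ids integer vector of 0-based token ids
#' @param vocab a [TokenVocabulary-class]
#' @return character SMILES string
#' @export
decodeSequence <- function(ids, vocab) {
  ids <- ids[ids > 3L]
  paste(vocab@tokens[ids + 1L], collapse = "")
}

#' Create molecule records
#'
#' The corpus atom: an id, a canonical SMILES and a class label. Input
#' SMILES are canonicalized (the canonical form is a fixed point).
#'
#' @param smiles character vector of SMILES
#' @param id optional ids (default \code{mol00001}, ...)
#' @param label class labels, one of drug, metabolite, fluorophore,
#'   natural_product, other (recycled)
#' @param canonicalize set \code{FALSE} when input is already canonical
#' @return data.frame with columns \code{id}, \code{smiles}, \code{label}
#' @export
moleculeRecords <- function(smiles, id = NULL, label = "other",
                            canonicalize = TRUE) {
  n <- length(smiles)
  if (is.null(id)) id <- sprintf("mol%05d", seq_len(n))
  if (anyDuplicated(id)) stop("duplicate record ids")
  label <- rep_len(as.character(label), n)
  bad <- setdiff(unique(label), .LABELS)
  if (length(bad))
    stop("unknown label(s): ", paste(bad, collapse = ", "))
  if (canonicalize) smiles <- canonicalizeSmiles(smiles)
  data.frame(id = as.character(id), smiles = smiles, label = label,
             stringsAsFactors = FALSE)
}

#' Read a SMILES corpus from disk
#'
#' Supports plain \code{.smi} files (one SMILES per line with an optional
#' whitespace-separated identifier) and CSV files with a header containing
#' \code{smiles} and optionally \code{label} and \code{id} columns.
#'
#' @param path file path
#' @param format \code{"auto"} decides by extension
#' @param canonicalize canonicalize on read (default TRUE)
#' @return molecule records as from [moleculeRecords()]
#' @export
readMolecules <- function(path, format = c("auto", "smi", "csv"),
                          canonicalize = TRUE) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "smi"
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!"smiles" %in% names(df))
      stop("CSV must have a 'smiles' column: ", path)
    moleculeRecords(df$smiles,
                    id = if ("id" %in% names(df)) df$id else NULL,
                    label = if ("label" %in% names(df)) df$label else "other",
                    canonicalize = canonicalize)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (!length(lines)) stop("no SMILES in ", path)
    parts <- strsplit(lines, "[[:space:]]+")
    smi <- vapply(parts, `[[`, "", 1L)
    ids <- vapply(parts, function(p) if (length(p) > 1L) p[2L] else
      NA_character_, character(1))
    moleculeRecords(smi, id = if (all(!is.na(ids))) ids else NULL,
                    canonicalize = canonicalize)
  }
}

#' Write a corpus to CSV
#' @param records molecule records
#' @param path output CSV path
#' @return invisibly, the path
#' @export
writeMolecules <- function(records, path) {
  utils::write.csv(records[, c("smiles", "label", "id")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Persist a vocabulary as JSON
#'
#' The on-disk form is a single JSON object mapping each token to its
#' 0-based index; byte-identical for identical vocabularies.
#'
#' @param vocab a [TokenVocabulary-class]
#' @param path output path
#' @return invisibly, the path
#' @export
writeVocabulary <- function(vocab, path) {
  m <- as.list(seq_along(vocab@tokens) - 1L)
  names(m) <- vocab@tokens
  write_json(m, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a vocabulary written by [writeVocabulary()]
#' @param path JSON path
#' @return a [TokenVocabulary-class]
#' @export
readVocabulary <- function(path) {
  m <- read_json(path)
  toks <- names(sort(unlist(m)))
  new("TokenVocabulary", tokens = toks)
}

# Stable hash of a vocabulary (stored in checkpoints, verified on load).
.vocabHash <- function(vocab) digest::digest(vocab@tokens, algo = "sha256")
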