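# Synthetic scaffold-family corpora. Each family is one ring scaffold
# (benzene, cyclohexane, pyridine) decorated with sampled substituent
# pairs, giving small, valid, labelled SMILES sets with controlled
# within-family structural similarity -- a desk-scale stand-in for real
# drug/metabolite/fluorophore/natural-product corpora. Scaffolds have at
# least six heavy atoms and asymmetric substitution so that enumeration
# yields genuinely distinct SMILES strings.

#' Describe a scaffold family
#'
#' @param scaffold SMILES template with substitution points \code{{A}} and
#'   optionally \code{{B}}
#' @param substituents SMILES fragments valid at the substitution points
#' @param nMembers molecules to generate
#' @param label class label for the family's records
#' @return a \code{familySpec} list
#' @export
familySpec <- function(scaffold, substituents, nMembers = 8L,
                       label = "other") {
  stopifnot(grepl("{A}", scaffold, fixed = TRUE))
  structure(list(scaffold = scaffold, substituents = substituents,
                 nMembers = as.integer(nMembers), label = label),
            class = "familySpec")
}

#' Default benzene / cyclohexane / pyridine family specifications
#' @param nMembers molecules per family
#' @return list of three [familySpec()] objects
#' @export
defaultFamilySpecs <- function(nMembers = 8L) {
  subs <- c("C", "CC", "O", "N", "CO", "Cl", "C(C)C", "OC", "CN", "CCC")
  list(
    familySpec("c1cc({A})ccc1{B}", subs, nMembers, "drug"),
    familySpec("C1CC({A})CCC1{B}", subs, nMembers, "metabolite"),
    familySpec("c1nc({A})ccc1{B}", subs, nMembers, "natural_product"))
}

#' Generate labelled scaffold-family molecules
#'
#' Samples substituent combinations into each scaffold, canonicalizes and
#' de-duplicates (symmetric placements can collide on the same molecule),
#' and keeps drawing until \code{nMembers} distinct molecules exist.
#' Deterministic under a seed.
#'
#' @param specs list of [familySpec()] objects
#' @param seed optional seed (caller RNG restored)
#' @return molecule records with an extra \code{family} column
#' @export
generateFamilies <- function(specs, seed = NULL) {
  if (!length(specs)) stop("no family specs")
  .withSeed(seed, {
    out <- list()
    for (f in seq_along(specs)) {
      sp <- specs[[f]]
      canonicalizeSmiles(sub("{B}", "", sub("{A}", "", sp$scaffold,
                                            fixed = TRUE), fixed = TRUE))
      seen <- character(0)
      guard <- 0L
      while (length(seen) < sp$nMembers) {
        guard <- guard + 1L
        if (guard > 200L * sp$nMembers)
          stop("family ", f, ": cannot reach ", sp$nMembers,
               " distinct molecules")
        a <- sample(sp$substituents, 1L)
        b <- sample(sp$substituents, 1L)
        smi <- sub("{A}", a, sp$scaffold, fixed = TRUE)
        smi <- sub("{B}", b, smi, fixed = TRUE)
        can <- canonicalizeSmiles(smi)
        if (!(can %in% seen)) seen <- c(seen, can)
      }
      df <- moleculeRecords(seen,
                            id = sprintf("fam%d_%02d", f,
                                         seq_along(seen)),
                            label = sp$label, canonicalize = FALSE)
      df$family <- paste0("family", f)
      out[[f]] <- df
    }
    do.call(rbind, out)
  })
}

#' Frozen desk-scale fixture corpora
#'
#' \code{tiny}: five short molecules for memorization probes.
#' \code{small}: three scaffold families of eight molecules each
#' (benzene / cyclohexane / pyridine) for clustering-recovery probes.
#' Both are generated from frozen seeds and are identical across runs.
#'
#' @param size \code{"tiny"} or \code{"small"}
#' @return molecule records
#' @export
defaultFixture <- function(size = c("tiny", "small")) {
  size <- match.arg(size)
  if (size == "tiny") {
    df <- moleculeRecords(
      c("CCO", "CC(=O)O", "c1ccccc1", "CC(C)CO", "CCOC"),
      id = paste0("tiny", 1:5), label = "other")
    return(df)
  }
  generateFamilies(defaultFamilySpecs(8L), seed = 20210403L)
}

#' Large corpus of recycled records for split/batch arithmetic
#'
#' Replicates fixture SMILES under fresh unique ids to reach any corpus
#' size without chemistry work; record-level operations (splitting,
#' batching) only count rows.
#'
#' @param n number of records
#' @param base molecule records to recycle (default: the small fixture)
#' @return molecule records with \code{n} rows
#' @export
recycledCorpus <- function(n, base = defaultFixture("small")) {
  i <- rep_len(seq_len(nrow(base)), n)
  data.frame(id = sprintf("syn%06d", seq_len(n)),
             smiles = base$smiles[i], label = base$label[i],
             stringsAsFactors = FALSE)
}
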