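# Minimal SMILES molecular-graph parser and writer.
#
# This exists for one purpose: Bjerrum-style enumeration, i.e. re-writing a
# molecule's SMILES from a random atom ordering so that many distinct strings
# denote the same molecular graph. Atom tokens are preserved verbatim
# (bracket atoms included), bond orders travel with their edges, and ring
# closures are re-numbered, so the rewritten string canonicalizes back to
# the parent. Canonicalization itself is delegated to Open Babel; this
# parser is also the package's strict validity check, since Open Babel is
# lenient about malformed input.

.BOND_SYMS <- c("-", "=", "#", "$", ":", "/", "\\")

# Parse a SMILES string into an atom/bond graph.
# Returns list(tokens = character per atom, aromatic = logical per atom,
#              bonds = data.frame(a, b, sym)).
.parseSmiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || !nzchar(smiles))
    stop("SMILES must be a single non-empty string")
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n <- length(chars)
  atoms <- character(0); aromatic <- logical(0)
  bonds <- list()
  prev <- 0L                      # index of previous atom (0 = none)
  pend <- ""                      # pending bond symbol
  stack <- integer(0)             # branch stack
  rings <- list()                 # open ring closures: digit -> c(atom, sym)
  i <- 1L
  addAtom <- function(tok, arom) {
    atoms[[length(atoms) + 1L]] <<- tok
    aromatic[[length(aromatic) + 1L]] <<- arom
    a <- length(atoms)
    if (prev > 0L)
      bonds[[length(bonds) + 1L]] <<- list(a = prev, b = a, sym = pend)
    prev <<- a
    pend <<- ""
  }
  closeRing <- function(key) {
    if (!is.null(rings[[key]])) {
      op <- rings[[key]]
      sym <- if (nzchar(pend)) pend else op$sym
      if (nzchar(op$sym) && nzchar(pend) && op$sym != pend)
        stop("conflicting bond symbols on ring closure ", key,
             " in '", smiles, "'")
      if (op$atom == prev)
        stop("ring bond to self in '", smiles, "'")
      bonds[[length(bonds) + 1L]] <<- list(a = op$atom, b = prev, sym = sym)
      rings[[key]] <<- NULL
      pend <<- ""
    } else {
      if (prev == 0L) stop("ring closure before any atom in '", smiles, "'")
      rings[[key]] <<- list(atom = prev, sym = pend)
      pend <<- ""
    }
  }
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unclosed bracket atom in '", smiles, "'")
      tok <- paste(chars[i:j], collapse = "")
      inner <- sub("^\\[[0-9]*", "", tok)
      addAtom(tok, grepl("^[a-z]", inner))
      i <- j + 1L
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
      if (two %in% c("Cl", "Br")) {
        addAtom(two, FALSE); i <- i + 2L
      } else {
        addAtom(ch, FALSE); i <- i + 1L
      }
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      addAtom(ch, TRUE); i <- i + 1L
    } else if (ch %in% .BOND_SYMS) {
      pend <- ch; i <- i + 1L
    } else if (ch == "(") {
      if (prev == 0L) stop("branch before any atom in '", smiles, "'")
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L)
        stop("unbalanced ')' in '", smiles, "'")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (grepl("^[0-9]$", ch)) {
      closeRing(ch); i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n) stop("truncated %nn ring closure in '", smiles, "'")
      closeRing(paste(chars[(i + 1L):(i + 2L)], collapse = ""))
      i <- i + 3L
    } else if (ch == ".") {
      stop("disconnected (dotted) SMILES are not supported: '", smiles, "'")
    } else {
      stop("unexpected character '", ch, "' in SMILES '", smiles, "'")
    }
  }
  if (length(stack) > 0L) stop("unbalanced '(' in '", smiles, "'")
  if (length(rings) > 0L)
    stop("unclosed ring bond(s) ", paste(names(rings), collapse = ","),
         " in '", smiles, "'")
  if (length(atoms) == 0L) stop("no atoms in '", smiles, "'")
  bdf <- if (length(bonds))
    data.frame(a = vapply(bonds, `[[`, 1L, "a"),
               b = vapply(bonds, `[[`, 1L, "b"),
               sym = vapply(bonds, `[[`, "", "sym"),
               stringsAsFactors = FALSE)
  else data.frame(a = integer(0), b = integer(0), sym = character(0))
  list(tokens = atoms, aromatic = aromatic, bonds = bdf)
}

# Write a SMILES string from a graph, rooted at `root`, visiting neighbors
# in random order (consumes the R RNG stream). Ring-closure digits are
# re-assigned; their bond symbol is emitted at both ends.
.writeSmiles <- function(graph, root = 1L) {
  na <- length(graph$tokens)
  adj <- vector("list", na)
  nb <- nrow(graph$bonds)
  if (nb > 0) for (e in seq_len(nb)) {
    a <- graph$bonds$a[e]; b <- graph$bonds$b[e]
    adj[[a]] <- c(adj[[a]], list(list(to = b, sym = graph$bonds$sym[e], e = e)))
    adj[[b]] <- c(adj[[b]], list(list(to = a, sym = graph$bonds$sym[e], e = e)))
  }
  visited <- logical(na)
  treeKids <- vector("list", na)    # per atom: list of (to, sym)
  ringAt <- vector("list", na)      # per atom: list of (key, sym)
  edgeUsed <- logical(max(nb, 1L))
  ringCount <- 0L
  # iterative DFS to avoid deep recursion on long chains
  stack <- list(list(atom = root, parent = 0L))
  visited[root] <- TRUE
  order <- integer(0)
  while (length(stack)) {
    fr <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    a <- fr$atom
    order <- c(order, a)
    nbrs <- adj[[a]]
    if (length(nbrs) > 1L) nbrs <- nbrs[sample.int(length(nbrs))]
    kids <- list()
    for (x in nbrs) {
      if (edgeUsed[x$e]) next
      if (visited[x$to]) {          # ring-closure (back) edge
        edgeUsed[x$e] <- TRUE
        ringCount <- ringCount + 1L
        key <- ringCount
        ringAt[[a]] <- c(ringAt[[a]], list(list(key = key, sym = x$sym)))
        ringAt[[x$to]] <- c(ringAt[[x$to]], list(list(key = key, sym = x$sym)))
      } else {
        edgeUsed[x$e] <- TRUE
        visited[x$to] <- TRUE
        kids <- c(kids, list(x))
      }
    }
    treeKids[[a]] <- kids
    # push in reverse so the first sampled child is emitted first
    if (length(kids)) for (k in rev(seq_along(kids)))
      stack[[length(stack) + 1L]] <- list(atom = kids[[k]]$to, parent = a)
  }
  if (!all(visited))
    stop("molecular graph is disconnected; cannot write a single SMILES")
  bondStr <- function(sym) {
    if (sym %in% c("/", "\\")) "" else sym   # stereo direction not preserved
  }
  digitStr <- function(key) if (key > 9L) sprintf("%%%02d", key) else
    as.character(key)
  # emit, again iteratively via an output program
  out <- character(0)
  emit <- function(a) {
    # returns the string for the subtree rooted at a (molecule sizes here
    # are small, recursion depth == longest chain)
    s <- graph$tokens[a]
    if (length(ringAt[[a]]))
      for (r in ringAt[[a]]) s <- paste0(s, bondStr(r$sym), digitStr(r$key))
    kids <- treeKids[[a]]
    nk <- length(kids)
    if (nk) for (k in seq_len(nk)) {
      sub <- paste0(bondStr(kids[[k]]$sym), emit(kids[[k]]$to))
      s <- if (k < nk) paste0(s, "(", sub, ")") else paste0(s, sub)
    }
    s
  }
  emit(root)
}

# TRUE when enumeration would silently change the molecule's meaning.
.hasStereo <- function(smiles) {
  grepl("[/\\\\]", smiles) || grepl("@", smiles, fixed = TRUE)
}
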