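# Independent oracles and small fixture builders used across the suite.
# Each oracle deliberately takes a different computational route from the
# implementation it checks.

# Naive leftmost-longest annotator: exhaustive comparison of every
# dictionary surface form against every token span (no hashed lookup).
naiveAnnotate <- function(text, dict, docId = "doc1") {
  toks <- tokenizeText(text)
  nt <- nrow(toks)
  forms <- unique(dict@entries$normform)
  out <- list()
  i <- 1L
  stems <- if (dict@stemmed) snowballStem(toks$token) else NULL
  while (i <= nt) {
    best <- 0L
    for (j in seq(i, nt)) {
      key <- paste(toks$token[i:j], collapse = " ")
      hit <- key %in% forms
      if (!hit && dict@stemmed)
        hit <- paste(stems[i:j], collapse = " ") %in% forms
      if (hit) best <- j
    }
    if (best > 0L) {
      key <- paste(toks$token[i:best], collapse = " ")
      rows <- dict@entries$normform == key
      if (!any(rows) && dict@stemmed) {
        skey <- paste(stems[i:best], collapse = " ")
        rows <- dict@entries$normform == skey
      }
      off <- toks$offset[i]
      len <- toks$offset[best] + toks$length[best] - off
      for (lab in unique(dict@entries$label[rows]))
        out[[length(out) + 1L]] <- data.frame(
          docId = docId, offset = off, length = len,
          matchedText = substr(text, off + 1L, off + len),
          conceptLabel = lab, sourceId = dict@sourceId,
          stringsAsFactors = FALSE)
      i <- best + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(out))
    return(data.frame(docId = character(), offset = integer(),
                      length = integer(), matchedText = character(),
                      conceptLabel = character(), sourceId = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$offset, res$sourceId, res$conceptLabel), , drop = FALSE]
}

# Brute-force all-pairs shared-synonym check between concepts of a list of
# TermSource objects; returns a data.frame of matched (node, node) pairs
# using global node numbering in source order.
bruteConceptPairs <- function(sources) {
  nodes <- do.call(rbind, lapply(seq_along(sources), function(s)
    data.frame(src = s, idx = seq_len(nConcepts(sources[[s]])))))
  forms <- function(s, i) {
    f <- tolower(trimws(c(conceptLabels(sources[[s]])[i],
                          synonyms(sources[[s]])[[i]])))
    unique(f[nzchar(f)])
  }
  pairs <- list()
  for (a in seq_len(nrow(nodes))) {
    for (b in seq_len(nrow(nodes))) {
      if (b <= a) next
      fa <- forms(nodes$src[a], nodes$idx[a])
      fb <- forms(nodes$src[b], nodes$idx[b])
      if (length(intersect(fa, fb)))
        pairs[[length(pairs) + 1L]] <- c(a, b)
    }
  }
  if (!length(pairs)) return(matrix(integer(), 0L, 2L))
  do.call(rbind, pairs)
}

# Brute-force co-occurrence recount from a stand-off annotation table.
recountFromAnnotations <- function(annotations, nDocsTotal, docIds,
                                   ontologyId, drugSourceId) {
  counts <- integer()
  nB <- 0L; nBC <- 0L
  for (d in docIds) {
    ann <- annotations[annotations$docId == d, , drop = FALSE]
    hasB <- any(ann$sourceId == ontologyId)
    drugsHere <- unique(ann$conceptLabel[ann$sourceId == drugSourceId])
    if (hasB) {
      nB <- nB + 1L
      if (length(drugsHere)) nBC <- nBC + 1L
      for (g in drugsHere) counts[g] <- (counts[g] %||% 0L) + 1L
    }
  }
  list(counts = counts, nDocsB = nB, nDocsBC = nBC)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

# All permutations of 1..n, plain recursion (independent of the package's
# enumeration code).
oraclePerms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in oraclePerms(n - 1L))
    for (pos in 0:(n - 1L))
      out[[length(out) + 1L]] <- as.integer(append(p, n, after = pos))
  out
}

# Footrule objective of a candidate ordering against a set of lists,
# written from the definition (no shared code with combineLists).
oracleObjective <- function(candidate, lists, space) {
  rankIn <- function(v) {
    r <- match(space, v); r[is.na(r)] <- length(v) + 1L; r
  }
  rc <- rankIn(candidate)
  mean(vapply(lists, function(l) sum(abs(rc - rankIn(l))), numeric(1)))
}

# A small OWL (RDF/XML) fixture written from scratch.
writeOwlFixture <- function(path) {
  writeLines(c(
    '<?xml version="1.0"?>',
    '<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"',
    '         xmlns:rdfs="http://www.w3.org/2000/01/rdf-schema#"',
    '         xmlns:owl="http://www.w3.org/2002/07/owl#"',
    '         xmlns:skos="http://www.w3.org/2004/02/skos/core#"',
    '         xmlns:oboInOwl="http://www.geneontology.org/formats/oboInOwl#">',
    '  <owl:Class rdf:about="http://example.org/onto#C1">',
    '    <rdfs:label>Seizure</rdfs:label>',
    '    <oboInOwl:hasExactSynonym>fit</oboInOwl:hasExactSynonym>',
    '    <oboInOwl:hasRelatedSynonym>convulsion</oboInOwl:hasRelatedSynonym>',
    '  </owl:Class>',
    '  <owl:Class rdf:about="http://example.org/onto#C2">',
    '    <rdfs:label>Aura</rdfs:label>',
    '    <skos:altLabel>warning sign</skos:altLabel>',
    '  </owl:Class>',
    '  <owl:Class rdf:about="http://example.org/onto#C3">',
    '    <rdfs:label>Status epilepticus</rdfs:label>',
    '  </owl:Class>',
    '  <owl:Class rdf:nodeID="anon1"/>',
    '</rdf:RDF>'), path)
  path
}

# Tiny tabular term-source file.
writeTabularFixture <- function(path, rows) {
  writeLines(c("id\tlabel\tsynonyms", rows), path)
  path
}
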