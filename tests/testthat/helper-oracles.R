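# Independent oracles used by the test suite. These deliberately do not share
# code with the package implementation.

# Plain recursive Levenshtein (exponential; only for tiny strings).
lev_recursive <- function(a, b) {
  na <- nchar(a); nb <- nchar(b)
  if (na == 0L) return(nb)
  if (nb == 0L) return(na)
  cost <- as.integer(substr(a, na, na) != substr(b, nb, nb))
  a1 <- substr(a, 1L, na - 1L)
  b1 <- substr(b, 1L, nb - 1L)
  min(lev_recursive(a1, b) + 1L, lev_recursive(a, b1) + 1L,
      lev_recursive(a1, b1) + cost)
}

# All strings over `alphabet` of length 0..maxlen (prefix-closed set).
all_strings_upto <- function(alphabet, maxlen) {
  out <- ""
  cur <- ""
  for (l in seq_len(maxlen)) {
    cur <- as.vector(t(outer(cur, alphabet, paste0)))
    out <- c(out, cur)
  }
  out
}

# Tabulated Levenshtein recurrence over a prefix-closed string set: applies
# d(ax, by) = min(d(a, by)+1, d(ax, b)+1, d(a, b)+[x != y]) bottom-up.
# Returns the full distance matrix.
lev_recurrence_oracle <- function(strings) {
  n <- length(strings)
  len <- nchar(strings)
  stopifnot("" %in% strings)
  parent <- ifelse(len == 0L, NA_integer_,
                   match(substr(strings, 1L, len - 1L), strings))
  last <- substr(strings, len, len)
  e <- match("", strings)
  groups <- split(seq_len(n), len)
  D <- matrix(NA_integer_, n, n)
  D[e, ] <- len
  D[, e] <- len
  for (i in order(len)) {
    if (len[i] == 0L) next
    rowpa <- D[parent[i], ]
    rowi <- D[i, ]
    for (l in seq_len(max(len))) {
      J <- groups[[as.character(l)]]
      cost <- as.integer(last[i] != last[J])
      rowi[J] <- pmin(rowpa[J] + 1L, rowi[parent[J]] + 1L,
                      rowpa[parent[J]] + cost)
    }
    D[i, ] <- rowi
  }
  D
}

# Exhaustive count of distinct reduced noun-verb languages: ordered
# assignments of 3 of 5 forms to the motions, times assignments of the two
# left-over forms to an admissible irregular cell pair.
exp3_language_space_size <- function() {
  forms <- c("jing", "rald", "nunj", "ferb", "yath")
  animals <- c("duck", "dog", "crocodile")
  motions <- c("straight", "bounce", "loop")
  cells <- expand.grid(a = animals, m = motions, stringsAsFactors = FALSE)
  sigs <- character(0)
  for (i in 1:5) for (j in 1:5) for (k in 1:5) {
    if (length(unique(c(i, j, k))) < 3L) next
    regs <- forms[c(i, j, k)]
    irr <- setdiff(forms, regs)
    for (c1 in seq_len(nrow(cells))) for (c2 in seq_len(nrow(cells))) {
      if (c1 == c2) next
      if (cells$a[c1] == cells$a[c2] || cells$m[c1] == cells$m[c2]) next
      sigs <- c(sigs, paste(paste(regs, collapse = ","),
                            cells$a[c1], cells$m[c1], irr[1],
                            cells$a[c2], cells$m[c2], irr[2]))
    }
  }
  length(unique(sigs))
}

# Canonical signature of a generated reduced language, for distribution and
# space-membership checks.
exp3_signature <- function(spec) {
  ic <- spec$irregular_cells
  ic <- ic[order(ic$animal, ic$motion), ]
  tab <- language_table(spec)
  paste(paste(tab$description, collapse = "|"),
        paste(ic$animal, ic$motion, ic$form, collapse = ";"))
}

# Irregular-cell placement of a generated language as a canonical string.
exp3_placement <- function(spec) {
  ic <- spec$irregular_cells
  key <- paste(ic$animal, ic$motion, sep = ".")
  paste(sort(key), collapse = "+")
}

# Scene data frame of the 18-scene set, plus a convenience splitter for the
# example data.
example_subset <- function(phase, word_class) {
  ex <- example_learner_suffixes()
  ex[ex$phase == phase & ex$word_class == word_class, ]
}
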