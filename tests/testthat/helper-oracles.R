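# Independent oracles used to cross-check the package's computations.
# Each takes a deliberately different route from the implementation it
# checks (linear algebra instead of seeded lookup, literal triple loops
# instead of vectorized scans), so agreement is evidence, not tautology.

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# --- mismatch search oracle: sparse one-hot linear algebra ---------------
# Every window of every text is one-hot encoded; matches per (window,
# query) come from a single sparse matrix product, and mismatches are
# k - matches. N encodes as the zero vector, so any N position can never
# match: the N-always-mismatches policy falls out of the encoding.
oracle_search <- function(queries, texts, max_mm = 2L) {
  k <- unique(nchar(queries))
  stopifnot(length(k) == 1L)
  win_tx <- integer(0); win_off <- integer(0); win_seq <- character(0)
  for (t in seq_along(texts)) {
    L <- nchar(texts[t])
    if (L < k) next
    st <- 0:(L - k)
    win_tx <- c(win_tx, rep(t, length(st)))
    win_off <- c(win_off, st)
    win_seq <- c(win_seq, substring(texts[t], st + 1L, st + k))
  }
  one_hot <- function(seqs) {
    m <- matrix(unlist(strsplit(seqs, "")), nrow = length(seqs), byrow = TRUE)
    codes <- match(m, c("A", "C", "G", "T"))          # column-major; N -> NA
    row <- rep(seq_len(nrow(m)), times = k)
    pos <- rep(seq_len(k), each = nrow(m))
    keep <- !is.na(codes)
    Matrix::sparseMatrix(i = row[keep], j = ((pos - 1L) * 4L + codes)[keep],
                         x = 1, dims = c(nrow(m), 4L * k))
  }
  X <- one_hot(win_seq)
  out <- vector("list", 0L)
  chunk <- 100L
  for (q0 in seq(1L, length(queries), by = chunk)) {
    qs <- q0:min(q0 + chunk - 1L, length(queries))
    M <- as.matrix(X %*% Matrix::t(one_hot(queries[qs])))   # matches
    hit <- which(k - M <= max_mm, arr.ind = TRUE)
    if (nrow(hit))
      out[[length(out) + 1L]] <- data.frame(
        query_idx = qs[hit[, 2]],
        text_idx = win_tx[hit[, 1]],
        offset = win_off[hit[, 1]],
        mismatches = as.integer(k - M[hit]))
  }
  res <- if (length(out)) do.call(rbind, out)
         else data.frame(query_idx = integer(), text_idx = integer(),
                         offset = integer(), mismatches = integer())
  res[order(res$query_idx, res$text_idx, res$offset), , drop = FALSE]
}

# gene-level summary recomputed from an oracle hit table
oracle_summary <- function(hits, gene_by_text, target_gene) {
  genes <- gene_by_text[hits$text_idx]
  keep <- genes != target_gene
  if (!any(keep)) return(c(genes_mm0 = 0L, genes_mm1 = 0L, genes_mm2 = 0L))
  mm <- tapply(hits$mismatches[keep], genes[keep], min)
  c(genes_mm0 = sum(mm == 0), genes_mm1 = sum(mm == 1), genes_mm2 = sum(mm == 2))
}

# --- nearest-neighbor summation oracle -----------------------------------
# Reads the shipped TSV directly and sums term by term with explicit
# indexing; no shared code with nn_duplex_dg()/nn_duplex_tm().
oracle_nn <- function(seq, set = "dna_dna", component = "dG37") {
  path <- system.file("extdata", paste0("nn_", set, ".tsv"),
                      package = "oligofunnel")
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  val <- function(dimer) tab[[component]][tab$dimer == dimer]
  total <- 0
  for (i in 1:(nchar(seq) - 1L))
    total <- total + val(substr(seq, i, i + 1L))
  if ("init" %in% tab$dimer) total <- total + val("init")
  for (b in c(substr(seq, 1L, 1L), substr(seq, nchar(seq), nchar(seq)))) {
    row <- if (b %in% c("A", "T")) "init_term_AT" else "init_term_GC"
    if (row %in% tab$dimer) total <- total + val(row)
  }
  total
}

# --- hairpin oracle: literal triple loop over (i, j, len) ----------------
oracle_hairpin <- function(seq, min_stem = 4L, min_loop = 3L) {
  b <- strsplit(seq, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  n <- length(b)
  best <- 0L
  for (i in 1:n) for (j in 1:n) {
    len <- 0L
    while (i + len <= n && j - len >= 1 && j - len - (i + len) - 1 >= min_loop &&
           b[i + len] == comp[[b[j - len]]])
      len <- len + 1L
    if (len > best) best <- len
  }
  if (best >= min_stem) best else 0L
}

# --- siRNA checklist oracle: literal restatement of the rule card --------
oracle_sirna_score <- function(sense) {
  ch <- strsplit(sense, "")[[1]]
  stopifnot(length(ch) == 19L)
  gc_pct <- 100 * sum(ch == "G" | ch == "C") / 19
  pts <- 0L
  if (gc_pct >= 30 && gc_pct <= 52) pts <- pts + 1L            # (a)
  for (p in 15:19) if (ch[p] == "A" || ch[p] == "T") pts <- pts + 1L  # (b)
  if (oracle_hairpin(sense, min_stem = 4L, min_loop = 3L) == 0L)
    pts <- pts + 1L                                            # (c)
  if (ch[19] == "A") pts <- pts + 1L                           # (d)
  if (ch[3] == "A") pts <- pts + 1L                            # (e)
  if (ch[10] == "T") pts <- pts + 1L                           # (f)
  if (ch[19] == "G" || ch[19] == "C") pts <- pts - 1L          # (g)
  if (ch[13] == "G") pts <- pts - 1L                           # (h)
  if (pts < 0L) 0L else pts
}

# --- self-dimer oracle: enumerate every antiparallel offset --------------
oracle_self_dimer <- function(seq, params = load_nn_params("dna_dna")) {
  b <- strsplit(seq, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  n <- length(b)
  best <- 0
  for (shift in (-(n - 1L)):(n - 1L)) {
    # strand A position i pairs reversed-copy position i + shift
    run <- 0L; start <- NA_integer_
    for (i in 1:(n + 1L)) {
      j <- n - (i + shift) + 1L   # partner index on the second copy
      paired <- i <= n && j >= 1L && j <= n && b[i] == comp[[b[j]]]
      if (paired) {
        if (run == 0L) start <- i
        run <- run + 1L
      } else {
        if (run >= 2L) {
          dg <- oracle_nn(substr(seq, start, start + run - 1L))
          if (dg < best) best <- dg
        }
        run <- 0L
      }
    }
  }
  best
}

# --- candidate construction shortcut for scoring/selection tests ---------
toy_candidates <- function(sense_seqs, design_type = "ASO", tx_id = "TX") {
  k <- nchar(sense_seqs[1])
  anti <- vapply(sense_seqs, reverse_complement, character(1), USE.NAMES = FALSE)
  structure(data.frame(
    oligo_id = sprintf("%s_%d", tx_id, seq_along(sense_seqs)),
    design_type = design_type,
    start = (seq_along(sense_seqs) - 1L) * k,
    end = seq_along(sense_seqs) * k,
    sense_seq = sense_seqs,
    antisense_seq = anti,
    has_ambiguity = grepl("N", sense_seqs),
    stringsAsFactors = FALSE),
    class = c("oligo_candidates", "data.frame"),
    primary_id = tx_id, primary_gene_id = "GX", k = k,
    add_tt_overhang = FALSE)
}
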