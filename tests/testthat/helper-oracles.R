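# Independent naive re-implementations used as oracles. These use
# plain string operations (no Biostrings, no Rcpp) and nested loops so
# they share no code path with the package.

# --- QC oracle -------------------------------------------------------

oracle_trim <- function(seq, adaptor, min_overlap = 3L, error_rate = 0.1) {
  len <- nchar(seq); alen <- nchar(adaptor)
  sc <- strsplit(seq, "")[[1L]]
  ac <- strsplit(adaptor, "")[[1L]]
  for (p in seq_len(len)) { # 1-based start of the adaptor occurrence
    m <- min(alen, len - p + 1L)
    if (m < min_overlap) break
    mm <- sum(sc[p:(p + m - 1L)] != ac[seq_len(m)])
    if (mm <= floor(error_rate * m)) {
      return(list(insert = substr(seq, 1L, p - 1L), found = TRUE))
    }
  }
  list(insert = seq, found = FALSE)
}

oracle_qc_status <- function(seq, qual, adaptor, min_overlap = 3L,
                             error_rate = 0.1, min_len = 15L, max_len = 45L,
                             q_threshold = 20L, min_q_fraction = 0.8) {
  tr <- oracle_trim(seq, adaptor, min_overlap, error_rate)
  if (!tr$found) return(list(status = "no_adaptor", insert = tr$insert))
  ins <- tr$insert
  if (nchar(ins) < min_len) return(list(status = "too_short", insert = ins))
  if (nchar(ins) > max_len) return(list(status = "too_long", insert = ins))
  q <- utf8ToInt(substr(qual, 1L, nchar(ins))) - 33L
  if (mean(q > q_threshold) < min_q_fraction) {
    return(list(status = "low_quality", insert = ins))
  }
  list(status = "pass", insert = ins)
}

# --- annotation oracle -----------------------------------------------

# all-references / all-offsets scan; per-offset Hamming distance via
# per-position comparison of the reference windows
oracle_hamming_hits <- function(seq, refs_bt, max_mm = 0L) {
  hits <- list()
  L <- nchar(seq)
  for (i in seq_len(nrow(refs_bt))) {
    ref <- refs_bt$sequence[i]
    if (nchar(ref) < L) next
    starts <- seq_len(nchar(ref) - L + 1L)
    wins <- substring(ref, starts, starts + L - 1L)
    if (max_mm == 0L) {
      mm <- ifelse(wins == seq, 0L, L)
    } else {
      mm <- integer(length(wins))
      for (j in seq_len(L)) {
        mm <- mm + (substring(wins, j, j) != substr(seq, j, j))
      }
    }
    keep <- which(mm <= max_mm)
    if (length(keep)) {
      hits[[length(hits) + 1L]] <- data.frame(
        ref_id = refs_bt$ref_id[i], offset = starts[keep],
        mismatches = mm[keep], stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) {
    return(data.frame(ref_id = character(), offset = integer(),
                      mismatches = integer()))
  }
  do.call(rbind, hits)
}

oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1L]]), collapse = "")
}

# full cascade + rescue, brute force
oracle_annotate <- function(seq, refs, genome,
                            order = c("miRNA", "rRNA", "tRNA", "piRNA", "other_ncRNA")) {
  sved <- c("4.5S", "5S", "5.8S", "12S", "16S", "18S", "28S", "45S")
  label <- function(bt, hits) {
    if (bt == "rRNA") {
      sv <- refs$svedberg_class[match(hits$ref_id, refs$ref_id)]
      cls <- sved[min(match(sv, sved))]
      return(list(biotype = "rsRNA", parent_class = cls, subtype = NA))
    }
    if (bt == "tRNA") {
      prec <- c("tsRNA_5p", "tsRNA_3p_CCA", "tsRNA_3p", "tsRNA_internal")
      subs <- character()
      for (k in seq_len(nrow(hits))) {
        Lp <- nchar(refs$sequence[refs$ref_id == hits$ref_id[k]])
        e <- hits$offset[k] + nchar(seq) - 1L
        subs <- c(subs, if (hits$offset[k] == 1L) "tsRNA_5p"
                  else if (e == Lp) "tsRNA_3p_CCA"
                  else if (e == Lp - 3L) "tsRNA_3p" else "tsRNA_internal")
      }
      return(list(biotype = "tsRNA", parent_class = NA,
                  subtype = prec[min(match(subs, prec))]))
    }
    list(biotype = bt, parent_class = NA, subtype = NA)
  }
  for (bt in order) {
    hits <- oracle_hamming_hits(seq, refs[refs$biotype == bt, ], 0L)
    if (nrow(hits)) {
      out <- label(bt, hits)
      out$rescued <- FALSE
      if (out$biotype == "piRNA") { # may still be a rescue candidate
        if (!grepl(seq, genome, fixed = TRUE) &&
            !grepl(oracle_revcomp(seq), genome, fixed = TRUE)) {
          for (bt2 in c("rRNA", "tRNA")) {
            h2 <- oracle_hamming_hits(seq, refs[refs$biotype == bt2, ], 1L)
            if (nrow(h2)) {
              out <- label(bt2, h2[h2$mismatches == min(h2$mismatches), ])
              out$rescued <- TRUE
              break
            }
          }
        }
      }
      return(out)
    }
  }
  out <- list(biotype = "no_annotation", parent_class = NA, subtype = NA,
              rescued = FALSE)
  if (!grepl(seq, genome, fixed = TRUE) &&
      !grepl(oracle_revcomp(seq), genome, fixed = TRUE)) {
    for (bt2 in c("rRNA", "tRNA")) {
      h2 <- oracle_hamming_hits(seq, refs[refs$biotype == bt2, ], 1L)
      if (nrow(h2)) {
        lab <- label(bt2, h2[h2$mismatches == min(h2$mismatches), ])
        lab$rescued <- TRUE
        return(lab)
      }
    }
  }
  out
}

# --- homology oracle -------------------------------------------------

oracle_seed_match <- function(q, s, min_cov = 0.9) {
  qc <- strsplit(q, "")[[1L]]
  sc <- strsplit(s, "")[[1L]]
  m <- 0L
  i <- 2L
  while (i <= length(qc) && i <= length(sc) && qc[i] == sc[i]) {
    m <- m + 1L
    i <- i + 1L
  }
  m / length(qc) > min_cov && m / length(sc) > min_cov
}

# --- shared fixtures -------------------------------------------------

rand_seq <- function(n, len) {
  vapply(rep_len(len, n), function(l)
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = ""),
    character(1))
}

# small toy reference set with 18S embedded in 45S and a processed His
# tRNA, plus a mini-genome
toy_refdb <- function(seed = 123) {
  set.seed(seed)
  r18 <- rand_seq(1, 120)
  r45 <- paste0(rand_seq(1, 40), r18, rand_seq(1, 60))
  raw_trna <- reference_set(
    ref_id = c("tRNA-His-1", "tRNA-Glu-1"),
    sequence = rand_seq(2, 72),
    biotype = "tRNA", amino_acid = c("His", "Glu"))
  trna <- preprocess_trna(raw_trna)
  refs <- rbind(
    reference_set(sprintf("mir-%02d", 1:4), rand_seq(4, 22), "miRNA"),
    reference_set(c("rRNA-18S", "rRNA-45S", "rRNA-5S"),
                  c(r18, r45, rand_seq(1, 90)), "rRNA",
                  svedberg_class = c("18S", "45S", "5S")),
    trna,
    reference_set(sprintf("piR-%02d", 1:6), rand_seq(6, 28), "piRNA"),
    reference_set("ncRNA-1", rand_seq(1, 100), "other_ncRNA"))
  genome <- paste(c(refs$sequence[refs$biotype != "tRNA"], raw_trna$sequence),
                  collapse = "")
  list(refs = refs, genome = genome, raw_trna = raw_trna)
}
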