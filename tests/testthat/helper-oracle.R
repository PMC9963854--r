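# Independent brute-force oracles for the pileup walker and the caller.
# Deliberately written as scalar per-read / per-site loops sharing no code
# with the package implementation.

oracle_pileup <- function(reads, region, reference, min_base_quality = 0) {
  chrom <- region$chromosome[1]
  lo <- region$start[1] + 1L
  hi <- region$end[1]
  quals_at <- list() # "pos|base" -> integer vector of quals
  for (i in seq_len(nrow(reads))) {
    r <- as.list(reads[i, ])
    if (r$rname != chrom) next
    fl <- r$flag
    unmapped <- (fl %/% 4L) %% 2L == 1L
    secondary <- (fl %/% 256L) %% 2L == 1L
    suppl <- (fl %/% 2048L) %% 2L == 1L
    if (unmapped || secondary || suppl) next
    if (r$cigar == "*" || !grepl("^([0-9]+[MIDNSHP=X])+$", r$cigar)) next
    rpos <- r$pos
    qpos <- 1L
    num <- ""
    for (ch in strsplit(r$cigar, "")[[1]]) {
      if (ch %in% as.character(0:9)) {
        num <- paste0(num, ch)
        next
      }
      l <- as.integer(num)
      num <- ""
      if (ch %in% c("M", "=", "X")) {
        for (j in seq_len(l)) {
          b <- toupper(substr(r$seq, qpos, qpos))
          q <- utf8ToInt(substr(r$qual, qpos, qpos)) - 33L
          if (rpos >= lo && rpos <= hi && q >= min_base_quality) {
            key <- paste0(rpos, "|", b)
            quals_at[[key]] <- c(quals_at[[key]], q)
          }
          rpos <- rpos + 1L
          qpos <- qpos + 1L
        }
      } else if (ch %in% c("I", "S")) {
        qpos <- qpos + l
      } else if (ch %in% c("D", "N")) {
        rpos <- rpos + l
      }
    }
  }
  if (length(quals_at) == 0L) {
    return(tibble::tibble(chromosome = character(), pos = integer(),
                          ref_base = character(), depth = integer(),
                          base = character(), count = integer(),
                          mean_qual = double()))
  }
  keys <- strsplit(names(quals_at), "|", fixed = TRUE)
  df <- tibble::tibble(
    chromosome = chrom,
    pos = vapply(keys, function(k) as.integer(k[1]), integer(1)),
    base = vapply(keys, function(k) k[2], character(1)),
    count = vapply(quals_at, length, integer(1)),
    mean_qual = vapply(quals_at, function(q) mean(q), double(1))
  )
  depth_at <- tapply(df$count, df$pos, sum)
  df$depth <- as.integer(depth_at[as.character(df$pos)])
  df$ref_base <- toupper(substring(reference[[chrom]], df$pos, df$pos))
  df[order(df$pos, df$base),
     c("chromosome", "pos", "ref_base", "depth", "base", "count", "mean_qual")]
}

oracle_call_variants <- function(pile, min_avg_qual = 20, min_var_freq = 0.01,
                                 min_reads2 = 10) {
  out <- list()
  for (p in sort(unique(pile$pos))) {
    rows <- pile[pile$pos == p, ]
    depth <- rows$depth[1]
    if (depth == 0) next
    alts <- rows[rows$base != rows$ref_base & rows$base %in% c("A", "C", "G", "T"), ]
    if (nrow(alts) == 0) next
    best <- NULL
    for (b in c("A", "C", "G", "T")) { # fixed tie order
      cand <- alts[alts$base == b, ]
      if (nrow(cand) == 1 && (is.null(best) || cand$count > best$count)) {
        best <- cand
      }
    }
    if (best$count >= min_reads2 &&
        best$count / depth >= min_var_freq &&
        best$mean_qual >= min_avg_qual) {
      best$alt_base <- best$base
      best$alt_reads <- best$count
      best$variant_frequency <- 100 * best$count / depth
      best$mean_alt_quality <- best$mean_qual
      out[[length(out) + 1L]] <-
        best[, c("chromosome", "pos", "ref_base", "alt_base", "depth",
                 "alt_reads", "variant_frequency", "mean_alt_quality")]
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(chromosome = character(), pos = integer(),
                          ref_base = character(), alt_base = character(),
                          depth = integer(), alt_reads = integer(),
                          variant_frequency = double(),
                          mean_alt_quality = double()))
  }
  dplyr::bind_rows(out)
}

# random SAM fixture generator: mixed CIGARs (soft clips, insertions,
# deletions), occasional secondary/unmapped records, mismatches vs a random
# reference
random_sam <- function(n_reads = 50, ref_len = 300, seed = 1) {
  withr::with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    refseq <- paste(sample(bases, ref_len, replace = TRUE), collapse = "")
    reads <- vector("list", n_reads)
    for (i in seq_len(n_reads)) {
      shape <- sample(c("simple", "softclip", "del", "ins"), 1,
                      prob = c(0.55, 0.15, 0.15, 0.15))
      m1 <- sample(15:30, 1)
      pos <- sample.int(ref_len - 80L, 1)
      take_ref <- function(at, len) {
        s <- strsplit(substring(refseq, at, at + len - 1L), "")[[1]]
        flip <- runif(len) < 0.08
        s[flip] <- vapply(s[flip], function(b) sample(setdiff(bases, b), 1),
                          character(1))
        paste(s, collapse = "")
      }
      rand_seq <- function(len) paste(sample(bases, len, replace = TRUE),
                                      collapse = "")
      if (shape == "simple") {
        cigar <- sprintf("%dM", m1)
        seq <- take_ref(pos, m1)
      } else if (shape == "softclip") {
        sc <- sample(3:6, 1)
        cigar <- sprintf("%dS%dM", sc, m1)
        seq <- paste0(rand_seq(sc), take_ref(pos, m1))
      } else if (shape == "del") {
        d <- sample(1:4, 1)
        m2 <- sample(10:20, 1)
        cigar <- sprintf("%dM%dD%dM", m1, d, m2)
        seq <- paste0(take_ref(pos, m1), take_ref(pos + m1 + d, m2))
      } else {
        ins <- sample(1:4, 1)
        m2 <- sample(10:20, 1)
        cigar <- sprintf("%dM%dI%dM", m1, ins, m2)
        seq <- paste0(take_ref(pos, m1), rand_seq(ins), take_ref(pos + m1, m2))
      }
      flag <- sample(c(0L, 0L, 0L, 0L, 0L, 0L, 256L, 4L), 1)
      qlen <- nchar(seq)
      qual <- intToUtf8(sample(2:41, qlen, replace = TRUE) + 33L)
      reads[[i]] <- tibble::tibble(
        qname = sprintf("r%03d", i), flag = flag, rname = "ref",
        pos = pos, mapq = 60L, cigar = cigar, rnext = "*", pnext = 0L,
        tlen = 0L, seq = seq, qual = qual)
    }
  })
  list(reads = dplyr::bind_rows(reads), reference = c(ref = refseq),
       region = tibble::tibble(chromosome = "ref", start = 0L,
                               end = ref_len))
}
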