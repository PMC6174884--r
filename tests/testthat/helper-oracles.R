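# Independent brute-force oracles used to validate the package's
# implementations on small inputs. These deliberately share no code with
# the functions they check.

# position-by-position Hamming scan over both strands: for every 20-nt
# window, count mismatches against the protospacer and test the 3-nt PAM
naiveOffTargetScan <- function(genomeChars, protospacer, pamPattern,
                               maxMismatches, seedLength = 12L) {
  revcomp <- function(chars) rev(c(A = "T", C = "G", G = "C", T = "A",
                                   N = "N")[chars])
  pamChars <- strsplit(pamPattern, "")[[1L]]
  pamSets <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
                  Y = c("C", "T"), N = c("A", "C", "G", "T"))
  guide <- strsplit(protospacer, "")[[1L]]
  out <- NULL
  for (chromName in names(genomeChars)) {
    chars <- genomeChars[[chromName]]
    L <- length(chars)
    for (strand in c("+", "-")) {
      for (s in seq_len(L - 19L)) {          # 1-based window [s, s+19]
        if (strand == "+") {
          if (s + 22L > L) next
          win <- chars[s:(s + 19L)]
          pam <- chars[(s + 20L):(s + 22L)]
        } else {
          if (s < 4L) next
          win <- revcomp(chars[s:(s + 19L)])
          pam <- revcomp(chars[(s - 3L):(s - 1L)])
        }
        if (any(win == "N") || any(pam == "N")) next
        pamOk <- all(vapply(seq_len(3L), function(k)
          pam[k] %in% pamSets[[pamChars[k]]], logical(1L)))
        if (!pamOk) next
        mm <- sum(win != guide)
        if (mm > maxMismatches) next
        seedIdx <- (20L - seedLength + 1L):20L
        out <- rbind(out, data.frame(
          chrom = chromName, start = s, strand = strand,
          siteSeq = paste(win, collapse = ""),
          pamSeq = paste(pam, collapse = ""),
          mismatches = mm, seedMismatches = sum(win[seedIdx] != guide[seedIdx]),
          stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(out)) return(out)
  out[order(out$chrom, out$start, out$strand), , drop = FALSE]
}

offTargetsAsDf <- function(gr) {
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                   start = BiocGenerics::start(gr),
                   strand = as.character(BiocGenerics::strand(gr)),
                   siteSeq = gr$siteSeq, pamSeq = gr$pamSeq,
                   mismatches = gr$mismatches,
                   seedMismatches = gr$seedMismatches,
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}

# nested-loop shared/specific partition by exact key equality
naivePartition <- function(wtRecords, mutRecords) {
  wk <- variantKey(wtRecords); mk <- variantKey(mutRecords)
  shared <- character(); wtOnly <- character(); mutOnly <- character()
  for (k in wk) {
    if (any(mk == k)) shared <- c(shared, k) else wtOnly <- c(wtOnly, k)
  }
  for (k in mk) if (!any(wk == k)) mutOnly <- c(mutOnly, k)
  list(shared = shared, wtOnly = wtOnly, mutOnly = mutOnly)
}

# all-pairs SV matcher: enumerate every admissible pair, then take a
# globally greedy assignment by breakpoint distance
naiveSvCompare <- function(wt, mut, tolerance = 1000, minOverlap = 0.5) {
  pairs <- NULL
  for (i in seq_len(nrow(wt))) for (j in seq_len(nrow(mut))) {
    a <- wt[i, ]; b <- mut[j, ]
    if (a$type != b$type || a$chrom1 != b$chrom1 || a$chrom2 != b$chrom2)
      next
    if (abs(a$pos1 - b$pos1) > tolerance || abs(a$pos2 - b$pos2) > tolerance)
      next
    if (a$type != "CTX") {
      ov <- min(a$pos2, b$pos2) - max(a$pos1, b$pos1)
      if (ov <= 0 || ov / (a$pos2 - a$pos1) < minOverlap ||
          ov / (b$pos2 - b$pos1) < minOverlap) next
    }
    pairs <- rbind(pairs, data.frame(
      i = i, j = j, d = abs(a$pos1 - b$pos1) + abs(a$pos2 - b$pos2)))
  }
  wtM <- logical(nrow(wt)); mutM <- logical(nrow(mut))
  if (!is.null(pairs)) {
    pairs <- pairs[order(pairs$d), , drop = FALSE]
    for (r in seq_len(nrow(pairs))) {
      if (!wtM[pairs$i[r]] && !mutM[pairs$j[r]]) {
        wtM[pairs$i[r]] <- TRUE; mutM[pairs$j[r]] <- TRUE
      }
    }
  }
  list(wtSpecific = which(!wtM), mutSpecific = which(!mutM),
       nShared = sum(wtM))
}

# deterministic small genome for guide tests: random background with a
# planted protospacer+PAM, redrawn until the only <= maxMismatches match
# is the planted one (checked with the naive scan)
plantedGenome <- function(protospacer, pam = "AGG", length = 5000L,
                          maxMismatches = 2L, seed = 1L) {
  set.seed(seed)
  repeat {
    chars <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
    at <- sample(seq(100L, length - 130L), 1L)
    chars[at:(at + 19L)] <- strsplit(protospacer, "")[[1L]]
    chars[(at + 20L):(at + 22L)] <- strsplit(pam, "")[[1L]]
    hits <- naiveOffTargetScan(list(chr1 = chars), protospacer, "NGG",
                               maxMismatches)
    if (nrow(hits) == 1L)
      return(list(genome = setNames(paste(chars, collapse = ""), "chr1"),
                  at = at))
  }
}

testVariants <- function(chrom, pos, genotype = "0/1", ref = "A", alt = "T",
                         qual = 100, depth = 50, class = "SNP") {
  n <- length(pos)
  data.frame(chrom = rep_len(chrom, n), pos = as.integer(pos),
             ref = rep_len(ref, n), alt = rep_len(alt, n),
             qual = rep_len(qual, n), genotype = rep_len(genotype, n),
             depth = as.integer(rep_len(depth, n)),
             class = rep_len(class, n))
}

# random background with mutated protospacer copies planted at chosen
# mismatch counts (valid PAM), on both strands; gives the off-target
# scanners a non-trivial site population to agree on
mismatchLadderGenome <- function(protospacer, length = 15000L,
                                 mismatchCounts = c(0:5), seed = 1L) {
  set.seed(seed)
  chars <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
  guide <- strsplit(protospacer, "")[[1L]]
  slots <- seq(200L, length - 200L, by = 400L)
  slots <- sample(slots, 2L * base::length(mismatchCounts))
  k <- 1L
  for (m in mismatchCounts) {
    for (strand in c("+", "-")) {
      site <- guide
      if (m > 0L) for (p in sample(20L, m))
        site[p] <- sample(setdiff(c("A", "C", "G", "T"), site[p]), 1L)
      pam <- c(sample(c("A", "C", "G", "T"), 1L), "G", "G")
      s <- slots[k]; k <- k + 1L
      if (strand == "+") {
        chars[s:(s + 19L)] <- site
        chars[(s + 20L):(s + 22L)] <- pam
      } else {
        rc <- function(x) rev(c(A = "T", C = "G", G = "C", T = "A")[x])
        chars[s:(s + 19L)] <- rc(site)
        chars[(s - 3L):(s - 1L)] <- rc(pam)
      }
    }
  }
  list(chars = list(chr1 = chars),
       genome = c(chr1 = paste(chars, collapse = "")))
}

flatCoverage <- function(chrom, length, depth, windowSize = 50000L) {
  start <- seq(0L, length - 1L, by = windowSize)
  data.frame(chrom = chrom, start = start,
             end = pmin(start + windowSize, length), meanDepth = depth)
}
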