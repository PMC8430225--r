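# PWM motif scanning with exact dynamic-programming p-values, promoter and
# enhancer region definition, and TF-lncRNA positive feedback loop calling
# (motif binding AND a significant ceRNA pair).

BASES <- c("A", "C", "G", "T")

#' Build a position weight matrix from base counts
#'
#' Count matrices (one row per motif position, columns A/C/G/T, or the
#' transpose) are converted to a frequency model with a pseudocount added to
#' every cell, then to a log2-odds matrix against the background. For
#' p-value computation the per-position scores are discretized to integers
#' on a fixed granularity (default 1/1000 of the total score range, rounding
#' column scores down) and the exact distribution of the integer word score
#' under i.i.d. background bases is computed by dynamic programming.
#'
#' @param counts Numeric matrix, w x 4 or 4 x 4-free transpose, columns
#'   (or rows) ordered A, C, G, T.
#' @param name Motif name (typically the TF id).
#' @param pseudocount Added to every count cell (default 0.1).
#' @param background Length-4 base probabilities (A, C, G, T), summing to 1.
#' @param granularity Number of integer score bins across the full range.
#' @return Object of class `lncnet_pwm`.
#' @export
pwm_from_counts <- function(counts, name = "motif", pseudocount = 0.1,
                            background = rep(0.25, 4), granularity = 1000) {
  counts <- as.matrix(counts)
  if (ncol(counts) != 4 && nrow(counts) == 4) counts <- t(counts)
  if (ncol(counts) != 4) lnc_validation_error("counts must have 4 base columns")
  if (any(counts < 0)) lnc_validation_error("counts must be non-negative")
  if (pseudocount <= 0) lnc_validation_error("pseudocount must be positive")
  background <- background / sum(background)
  if (any(background <= 0))
    lnc_validation_error("background probabilities must be positive")
  w <- nrow(counts)
  colnames(counts) <- BASES
  freq <- (counts + pseudocount) / (rowSums(counts) + 4 * pseudocount)
  log_odds <- log2(sweep(freq, 2, background, "/"))

  mins <- apply(log_odds, 1, min)
  maxs <- apply(log_odds, 1, max)
  min_total <- sum(mins)
  max_total <- sum(maxs)
  rng <- max_total - min_total
  if (rng > 0) {
    eps <- rng / granularity
    kmat <- floor(sweep(log_odds, 1, mins, "-") / eps + 1e-9)
    storage.mode(kmat) <- "integer"
    # integer score of an ambiguous base (log-odds 0, i.e. background)
    k_n <- as.integer(floor((0 - mins) / eps + 1e-9))
    kmax <- sum(apply(kmat, 1, max))
    # DP: exact pmf of the integer word score under background
    pmf <- c(1, numeric(kmax))
    for (j in seq_len(w)) {
      nxt <- numeric(kmax + 1)
      for (b in 1:4) {
        k <- kmat[j, b]
        nxt[(k + 1):(kmax + 1)] <- nxt[(k + 1):(kmax + 1)] +
          background[b] * pmf[1:(kmax + 1 - k)]
      }
      pmf <- nxt
    }
    tail_p <- rev(cumsum(rev(pmf)))
  } else {
    eps <- 0; kmat <- matrix(0L, w, 4, dimnames = list(NULL, BASES))
    k_n <- integer(w); kmax <- 0L; tail_p <- 1
  }
  structure(list(name = name, width = w, freq = freq, log_odds = log_odds,
                 background = setNames(background, BASES),
                 pseudocount = pseudocount, granularity = granularity,
                 eps = eps, min_total = min_total, max_total = max_total,
                 kmat = kmat, k_n = k_n, kmax = kmax, tail_p = tail_p),
            class = "lncnet_pwm")
}

#' @export
print.lncnet_pwm <- function(x, ...) {
  cat(sprintf("PWM '%s': width %d, score range [%.3f, %.3f] bits\n",
              x$name, x$width, x$min_total, x$max_total))
  invisible(x)
}

#' Exact p-value of a PWM score
#'
#' Returns `P(score(W) >= score)` for a random word `W` of the motif width
#' with i.i.d. background bases, computed from the dynamic-programming
#' distribution of the discretized score stored in the PWM. Scores at or
#' above the attainable maximum map to the top integer score, scores below
#' the attainable minimum give 1.
#'
#' @param pwm An [pwm_from_counts()] object.
#' @param score Score in bits (vectorized).
#' @return Probabilities in `(0, 1]`, non-increasing in `score`.
#' @export
score_pvalue <- function(pwm, score) {
  stopifnot(inherits(pwm, "lncnet_pwm"))
  vapply(score, function(s) {
    if (pwm$eps == 0) return(1)
    kq <- floor((s - pwm$min_total) / pwm$eps + 1e-9)
    if (kq <= 0) return(1)
    kq <- min(kq, pwm$kmax)
    pwm$tail_p[kq + 1]
  }, numeric(1))
}

# Internal: map a DNA string to integer codes A=1..T=4, anything else 0.
dna_codes <- function(s) {
  v <- match(strsplit(toupper(s), "", fixed = TRUE)[[1]],
             BASES, nomatch = 0L)
  as.integer(v)
}

# Internal: reverse complement of a character sequence.
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Internal: integer and bit scores of all windows of a coded sequence.
window_scores <- function(pwm, codes) {
  w <- pwm$width
  nw <- length(codes) - w + 1
  if (nw < 1) return(NULL)
  ik <- numeric(nw)
  sb <- numeric(nw)
  for (j in seq_len(w)) {
    cj <- codes[j:(j + nw - 1)]
    krow <- c(pwm$k_n[j], pwm$kmat[j, ])     # index 1 = ambiguous base
    lrow <- c(0, pwm$log_odds[j, ])
    ik <- ik + krow[cj + 1]
    sb <- sb + lrow[cj + 1]
  }
  list(int = ik, bits = sb)
}

#' Scan regions for PWM hits
#'
#' Every window of every region is scored on both strands (the minus strand
#' scores the reverse complement; the reported offset is the window start on
#' the plus strand, 0-based within the region). Ambiguous bases score 0
#' (background). Windows whose exact p-value is below `p_cutoff` are
#' returned, sorted by (region, offset, strand).
#'
#' @param pwm A single PWM or list of PWMs (one per TF).
#' @param sequences Named character vector of sequences (names match region
#'   `chrom`).
#' @param regions data.frame from [define_promoters()] /
#'   [assign_enhancers()] (columns chrom, start, end, role, owner_gene, and
#'   optionally name).
#' @param p_cutoff Report hits with `p < p_cutoff` (default 1e-4).
#' @return data.frame of hits: tf_id, region_id, chrom, region_start,
#'   region_end, role, owner_gene, offset, strand, score, p.
#' @export
scan_regions <- function(pwm, sequences, regions, p_cutoff = 1e-4) {
  if (inherits(pwm, "lncnet_pwm")) pwm <- list(pwm)
  if (!"name" %in% names(regions))
    regions$name <- paste0(regions$chrom, ":", regions$start, "-",
                           regions$end, ":", regions$owner_gene)
  out <- list()
  for (ri in seq_len(nrow(regions))) {
    chrom <- regions$chrom[ri]
    if (!chrom %in% names(sequences)) {
      warning("no sequence for region on '", chrom, "'; region skipped")
      next
    }
    seq_full <- sequences[[chrom]]
    s0 <- max(0L, regions$start[ri])
    e0 <- min(nchar(seq_full), regions$end[ri])
    if (e0 <= s0) next
    rseq <- substr(seq_full, s0 + 1, e0)
    len <- nchar(rseq)
    fwd <- dna_codes(rseq)
    rev_ <- dna_codes(revcomp(rseq))
    for (p in pwm) {
      w <- p$width
      for (strand in c("+", "-")) {
        ws <- window_scores(p, if (strand == "+") fwd else rev_)
        if (is.null(ws)) next
        pv <- if (p$eps == 0) rep(1, length(ws$int)) else
          p$tail_p[pmin(ws$int, p$kmax) + 1]
        hit <- which(pv < p_cutoff)
        if (!length(hit)) next
        offs <- if (strand == "+") hit - 1L else len - (hit - 1L) - w
        out[[length(out) + 1]] <- data.frame(
          tf_id = p$name, region_id = regions$name[ri], chrom = chrom,
          region_start = s0, region_end = e0, role = regions$role[ri],
          owner_gene = regions$owner_gene[ri], offset = offs,
          strand = strand, score = ws$bits[hit], p = pv[hit],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(tf_id = character(0), region_id = character(0),
                      chrom = character(0), region_start = integer(0),
                      region_end = integer(0), role = character(0),
                      owner_gene = character(0), offset = integer(0),
                      strand = character(0), score = numeric(0),
                      p = numeric(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$region_id, res$offset, res$strand), ]
  rownames(res) <- NULL
  res
}

#' Define lncRNA promoter regions around TSSs
#'
#' A promoter is the window `[TSS - flank, TSS + flank)` (0-based half-open,
#' clipped at zero) around each lncRNA transcription start site.
#'
#' @param tss_table data.frame with columns chrom, tss (0-based), lnc_id
#'   (and optionally strand).
#' @param flank Flank size in bp (default 2000).
#' @return Region data.frame (chrom, start, end, strand, role, owner_gene,
#'   name).
#' @export
define_promoters <- function(tss_table, flank = 2000) {
  if (flank <= 0) lnc_validation_error("flank must be positive")
  if (any(tss_table$tss < 0)) lnc_validation_error("negative TSS coordinate")
  data.frame(
    chrom = tss_table$chrom,
    start = pmax(0L, as.integer(tss_table$tss - flank)),
    end = as.integer(tss_table$tss + flank),
    strand = if ("strand" %in% names(tss_table)) tss_table$strand else ".",
    role = "promoter",
    owner_gene = tss_table$lnc_id,
    name = paste0(tss_table$lnc_id, "_promoter"),
    stringsAsFactors = FALSE)
}

#' Assign enhancers to lncRNAs by TSS distance
#'
#' An enhancer is assigned to every lncRNA on the same chromosome whose TSS
#' distance to the enhancer's nearest edge is strictly greater than
#' `min_dist` (i.e. outside the promoter window) and at most `max_dist`.
#' One enhancer may serve several lncRNAs.
#'
#' @param enhancers BED-style data.frame (chrom, start, end, name).
#' @param tss_table data.frame with columns chrom, tss, lnc_id.
#' @param min_dist Exclusive lower distance bound (default 2000).
#' @param max_dist Inclusive upper distance bound.
#' @return Region data.frame as in [define_promoters()], role "enhancer".
#' @export
assign_enhancers <- function(enhancers, tss_table, min_dist = 2000,
                             max_dist = 100000) {
  if (max_dist <= min_dist)
    lnc_validation_error("max_dist must exceed min_dist")
  out <- list()
  for (ei in seq_len(nrow(enhancers))) {
    same <- tss_table[tss_table$chrom == enhancers$chrom[ei], , drop = FALSE]
    if (!nrow(same)) next
    s <- enhancers$start[ei]; e <- enhancers$end[ei]
    d <- ifelse(same$tss < s, s - same$tss,
                ifelse(same$tss >= e, same$tss - e + 1L, 0L))
    sel <- which(d > min_dist & d <= max_dist)
    if (!length(sel)) next
    nm <- if ("name" %in% names(enhancers)) enhancers$name[ei] else
      paste0("enh_", ei)
    out[[length(out) + 1]] <- data.frame(
      chrom = enhancers$chrom[ei], start = s, end = e, strand = ".",
      role = "enhancer", owner_gene = same$lnc_id[sel],
      name = paste0(nm, "_", same$lnc_id[sel]), stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      role = character(0), owner_gene = character(0),
                      name = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Identify TF-lncRNA positive feedback loops
#'
#' A loop is emitted for a (TF, lncRNA) pair exactly when the pair is a
#' significant ceRNA pair AND at least one motif hit of that TF lies in a
#' promoter or enhancer owned by the lncRNA. `region_roles` records which
#' element types carried hits and `n_promoter_hits` / `n_enhancer_hits`
#' count motif occurrences per element type.
#'
#' @param cerna_pairs data.frame from [call_cerna_pairs()].
#' @param hits data.frame from [scan_regions()].
#' @return data.frame: tf_id, lnc_id, n_promoter_hits, n_enhancer_hits,
#'   region_roles, pcc, hyper_p.
#' @export
find_feedback_loops <- function(cerna_pairs, hits) {
  sig <- cerna_pairs[cerna_pairs$significant, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(sig))) {
    sel <- hits[hits$tf_id == sig$tf_id[i] &
                  hits$owner_gene == sig$lnc_id[i], , drop = FALSE]
    if (!nrow(sel)) next
    npro <- sum(sel$role == "promoter")
    nenh <- sum(sel$role == "enhancer")
    roles <- paste(sort(unique(sel$role)), collapse = "+")
    out[[length(out) + 1]] <- data.frame(
      tf_id = sig$tf_id[i], lnc_id = sig$lnc_id[i],
      n_promoter_hits = npro, n_enhancer_hits = nenh,
      region_roles = roles, pcc = sig$pcc[i], hyper_p = sig$hyper_p[i],
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(tf_id = character(0), lnc_id = character(0),
                      n_promoter_hits = integer(0),
                      n_enhancer_hits = integer(0),
                      region_roles = character(0), pcc = numeric(0),
                      hyper_p = numeric(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read / write motifs in minimal MEME format
#'
#' Supports the minimal MEME text format: a version line, optional
#' background frequencies, and per-motif letter-probability matrices with an
#' `nsites` attribute from which counts are recovered
#' (`counts = probs * nsites`).
#'
#' @param path MEME file path.
#' @return List of motifs; each has `name`, `counts` (w x 4), `nsites`, and
#'   the file-level `background`.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  bg <- rep(0.25, 4)
  bgi <- grep("^Background letter frequencies", lines)
  if (length(bgi)) {
    tok <- strsplit(trimws(lines[bgi[1] + 1]), "\\s+")[[1]]
    bg <- as.numeric(tok[c(2, 4, 6, 8)])
  }
  starts <- grep("^MOTIF\\b", lines)
  if (!length(starts)) lnc_stop("no MOTIF entries found in MEME file")
  motifs <- lapply(seq_along(starts), function(i) {
    name <- strsplit(trimws(lines[starts[i]]), "\\s+")[[1]][2]
    hi <- grep("^letter-probability matrix", lines[starts[i]:length(lines)])[1]
    hline <- lines[starts[i] + hi - 1]
    wm <- regmatches(hline, regexec("w=\\s*(\\d+)", hline))[[1]][2]
    nm <- regmatches(hline, regexec("nsites=\\s*(\\d+)", hline))[[1]][2]
    w <- as.integer(wm)
    nsites <- if (is.na(nm)) 20L else as.integer(nm)
    rows <- lines[(starts[i] + hi):(starts[i] + hi + w - 1)]
    probs <- do.call(rbind, lapply(rows, function(l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
    if (ncol(probs) != 4) lnc_stop("malformed MEME probability row")
    list(name = name, counts = probs * nsites, nsites = nsites,
         background = bg)
  })
  motifs
}

#' @rdname read_meme
#' @param motifs List of motifs (`name`, `counts`, `nsites` optional).
#' @param background Length-4 background probabilities.
#' @export
write_meme <- function(motifs, path, background = rep(0.25, 4)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "", "Background letter frequencies"), con)
  writeLines(sprintf("A %.5f C %.5f G %.5f T %.5f", background[1],
                     background[2], background[3], background[4]), con)
  for (mt in motifs) {
    counts <- as.matrix(mt$counts)
    if (ncol(counts) != 4 && nrow(counts) == 4) counts <- t(counts)
    nsites <- if (!is.null(mt$nsites)) mt$nsites else
      round(sum(counts[1, ]))
    probs <- counts / rowSums(counts)
    writeLines(c("", paste("MOTIF", mt$name),
                 sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                         nrow(probs), as.integer(nsites))), con)
    writeLines(apply(probs, 1, function(rr)
      sprintf(" %.6f %.6f %.6f %.6f", rr[1], rr[2], rr[3], rr[4])), con)
  }
  invisible(path)
}
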