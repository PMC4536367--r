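DNA_BASES <- c("A", "C", "G", "T")
SEED_CLASSES <- c("8mer", "7mer", "6mer", "none")

#' Normalise a nucleotide string to the DNA alphabet
#'
#' Uppercases and maps U to T so that miRNA (RNA) and genomic (DNA)
#' sequences share one alphabet for all motif operations.
#'
#' @param seq character vector of nucleotide strings.
#' @return character vector in `A/C/G/T` (plus any `N`s left untouched).
#' @export
as_dna <- function(seq) {
  chartr("Uu", "TT", toupper(seq))
}

#' Reverse complement in DNA space
#'
#' @param seq character vector of DNA strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(seq) {
  out <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(as_dna(seq))
  ))
  names(out) <- names(seq)
  out
}

#' Seed-site motif of a mature miRNA
#'
#' The k-mer a 3'UTR must contain to base-pair perfectly with miRNA
#' positions 2..k+1 (1-based from the miRNA 5' end): the reverse
#' complement of that subsequence, in DNA alphabet. Note this convention
#' (8mer = positions 2-9) differs from the TargetScan 7mer-A1/8mer-A1
#' definitions, which additionally anchor an A opposite position 1; here
#' every class is a pure seed-pairing match.
#'
#' @param mirna mature miRNA sequence (RNA or DNA string), length >= k+1.
#' @param k site length, one of 6, 7, 8 (pairing miRNA positions 2-7,
#'   2-8, 2-9 respectively).
#' @return single DNA string of length `k`.
#' @examples
#' seed_site_motif("GUGAAAUGUUUAGGACCACUAG", 8) # "ACATTTCA"
#' @export
seed_site_motif <- function(mirna, k) {
  stopifnot(length(mirna) == 1L, length(k) == 1L)
  if (!k %in% c(6L, 7L, 8L)) {
    stop("k must be 6, 7 or 8", call. = FALSE)
  }
  s <- as_dna(mirna)
  if (nchar(s) < k + 1L) {
    stop("miRNA sequence shorter than k + 1 nucleotides", call. = FALSE)
  }
  revcomp(substr(s, 2L, k + 1L))
}

#' Find all (possibly overlapping) motif occurrences
#'
#' @param seq DNA string to scan.
#' @param motif DNA motif (plain string, no ambiguity codes).
#' @return integer vector of 0-based start offsets, ascending.
#' @export
scan_sites <- function(seq, motif) {
  stopifnot(length(seq) == 1L, length(motif) == 1L, nchar(motif) >= 1L)
  seq <- as_dna(seq)
  motif <- as_dna(motif)
  if (is.na(seq) || nchar(seq) < nchar(motif)) return(integer(0))
  # lookahead so overlapping occurrences are all reported
  hits <- gregexpr(paste0("(?=", motif, ")"), seq, perl = TRUE)[[1L]]
  if (hits[1L] == -1L) return(integer(0))
  as.integer(hits) - 1L
}

#' Classify the seed class of a 3'UTR for one miRNA
#'
#' Returns the longest site class (8mer > 7mer > 6mer) whose motif occurs
#' at least once anywhere in the sequence, or `"none"`. Class is a
#' per-gene property; when a gene has several UTR isoforms the caller
#' should supply the longest one.
#'
#' @param utr_seq 3'UTR sequence (DNA string).
#' @param mirna mature miRNA sequence.
#' @return one of `"8mer"`, `"7mer"`, `"6mer"`, `"none"`.
#' @export
classify_seed_class <- function(utr_seq, mirna) {
  seq <- as_dna(utr_seq)
  for (k in c(8L, 7L, 6L)) {
    if (length(scan_sites(seq, seed_site_motif(mirna, k))) > 0L) {
      return(paste0(k, "mer"))
    }
  }
  "none"
}

#' Seed classes for a set of UTR sequences
#'
#' @param utrs named character vector of 3'UTR sequences (names = gene ids).
#' @param mirna mature miRNA sequence.
#' @return data.frame with columns `gene_id`, `seed_class`.
#' @export
classify_seed_classes <- function(utrs, mirna) {
  motifs <- vapply(c(8L, 7L, 6L), function(k) seed_site_motif(mirna, k), "")
  seqs <- as_dna(utrs)
  cls <- rep("none", length(seqs))
  for (i in seq_along(motifs)) {
    hit <- cls == "none" & grepl(motifs[i], seqs, fixed = TRUE)
    cls[hit] <- paste0(c(8L, 7L, 6L)[i], "mer")
  }
  data.frame(gene_id = names(utrs), seed_class = cls,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erickson Euler-path shuffle: the output is a uniform-ish
#' random sequence with exactly the same dinucleotide count vector as the
#' input (hence the same mononucleotide counts and the same first and
#' last base). Uses the current R RNG stream; seed with [set.seed()] for
#' reproducibility.
#'
#' The construction views each base as a vertex and each adjacent pair as
#' a directed edge; a random Eulerian path with the original endpoints is
#' drawn by sampling, for every non-terminal vertex, a "last exit" edge
#' such that the last-exit edges form a tree into the terminal vertex,
#' then permuting each vertex's remaining out-edges.
#'
#' @param seq DNA string of length >= 2.
#' @return shuffled DNA string.
#' @export
dinucleotide_shuffle <- function(seq) {
  s <- strsplit(as_dna(seq), "")[[1L]]
  n <- length(s)
  if (n < 2L) stop("sequence must have length >= 2", call. = FALSE)
  verts <- unique(s)
  if (length(verts) == 1L) return(paste(s, collapse = ""))
  from <- s[-n]
  to <- s[-1L]
  last <- s[n]
  # out-edge targets per vertex
  edges <- split(to, factor(from, levels = verts))
  nonterm <- setdiff(verts[lengths(edges) > 0L], last)

  pick_last_exits <- function() {
    le <- vapply(nonterm, function(v) {
      outs <- edges[[v]]
      outs[sample.int(length(outs), 1L)]
    }, "")
    names(le) <- nonterm
    # the chosen last-exit edges must form a tree rooted at `last`
    for (v in nonterm) {
      cur <- v
      steps <- 0L
      while (cur != last) {
        if (!cur %in% nonterm || steps > length(verts)) return(NULL)
        cur <- le[[cur]]
        steps <- steps + 1L
      }
    }
    le
  }
  repeat {
    le <- pick_last_exits()
    if (!is.null(le)) break
  }

  # order each vertex's out-edges: random permutation, last-exit edge last
  ordered <- edges
  for (v in verts) {
    outs <- edges[[v]]
    if (length(outs) == 0L) next
    if (v %in% nonterm) {
      i <- match(le[[v]], outs)
      rest <- outs[-i]
      ordered[[v]] <- c(rest[sample.int(length(rest))], outs[i])
    } else {
      ordered[[v]] <- outs[sample.int(length(outs))]
    }
  }

  # walk the Eulerian path
  ptr <- stats::setNames(rep(1L, length(verts)), verts)
  out <- character(n)
  out[1L] <- s[1L]
  cur <- s[1L]
  for (i in 2L:n) {
    nxt <- ordered[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    out[i] <- nxt
    cur <- nxt
  }
  paste(out, collapse = "")
}

#' Dinucleotide count vector of a sequence
#'
#' @param seq DNA string.
#' @return named integer vector over the 16 dinucleotides.
#' @export
dinucleotide_counts <- function(seq) {
  s <- strsplit(as_dna(seq), "")[[1L]]
  di <- paste0(s[-length(s)], s[-1L])
  lv <- as.vector(outer(DNA_BASES, DNA_BASES, paste0))
  table(factor(di, levels = sort(lv)))
}

all_kmers <- function(k) {
  stopifnot(k >= 1L, k <= 10L)
  grid <- do.call(expand.grid, c(rep(list(DNA_BASES), k),
                                 stringsAsFactors = FALSE))
  sort(do.call(paste0, rev(grid)))
}

# unique k-mers contained in each sequence, as one pooled factor count
kmer_containment_counts <- function(seqs, k, levels) {
  hits <- integer(length(levels))
  names(hits) <- levels
  for (s in seqs) {
    n <- nchar(s)
    if (n < k) next
    km <- unique(substring(s, 1:(n - k + 1L), k:n))
    km <- km[km %in% levels]  # drops windows containing N
    hits[km] <- hits[km] + 1L
  }
  hits
}

#' Exhaustive k-mer enrichment of foreground over background sequences
#'
#' For every k-mer, counts the number of foreground and background
#' sequences containing it at least once (set containment, not occurrence
#' counts) and computes a one-sided Fisher (hypergeometric) p-value for
#' the foreground containment count against the background containment
#' count. The background frequency is itself an estimate from a finite
#' sequence set, so the comparison is two-binomial; conditioning on the
#' combined count keeps the test valid when foreground and background
#' are exchangeable (e.g. the background is a dinucleotide shuffle of
#' the foreground). This is a transparent exhaustive replacement for de
#' novo motif discovery tools when the motif space (4^k) is enumerable.
#'
#' @param foreground character vector of DNA sequences (nonempty).
#' @param background character vector of DNA sequences (nonempty), e.g.
#'   dinucleotide shuffles of the foreground or random UTR windows.
#' @param k motif length, at most 10.
#' @return data.frame `motif`, `fg_count`, `bg_count`, `p`, `p_bonferroni`,
#'   sorted ascending by `p`, ties by descending `fg_count` then motif.
#' @export
motif_enrichment <- function(foreground, background, k) {
  if (length(foreground) == 0L) stop("empty foreground", call. = FALSE)
  if (length(background) == 0L) stop("empty background", call. = FALSE)
  stopifnot(k >= 1L, k <= 10L)
  fg <- as_dna(foreground)
  bg <- as_dna(background)
  motifs <- all_kmers(k)
  fg_count <- kmer_containment_counts(fg, k, motifs)
  bg_count <- kmer_containment_counts(bg, k, motifs)
  # one-sided Fisher via the hypergeometric upper tail:
  # P(X >= fg_count) drawing |fg| sequences from the pooled collection
  # with fg_count + bg_count carriers
  p <- stats::phyper(fg_count - 1L, fg_count + bg_count,
                     length(fg) + length(bg) - fg_count - bg_count,
                     length(fg), lower.tail = FALSE)
  tab <- data.frame(motif = motifs,
                    fg_count = as.integer(fg_count),
                    bg_count = as.integer(bg_count),
                    p = p,
                    p_bonferroni = pmin(1, p * length(motifs)),
                    stringsAsFactors = FALSE, row.names = NULL)
  tab[order(tab$p, -tab$fg_count, tab$motif), , drop = FALSE]
}
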