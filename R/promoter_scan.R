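# Consensus baculovirus promoter-motif scanning.
#
# Early promoters: a TATA box with a CAGT or CATT initiator 20-40 bp
# downstream of the TATA box's first base, the TATA box lying wholly within a
# window (default 180 nt) strictly upstream of - and not including - the A of
# the ATG.  Late promoters: (A/T/G)TAAG with its first base inside the same
# window.  Motifs must fit entirely inside the window; scanning is on the
# ORF's coding strand and wraps the origin on circular genomes.

# translate a simple IUPAC motif (subset) to a regex character-class pattern
.iupac_regex <- function(pattern) {
    map <- c(A = "A", C = "C", G = "G", T = "T", W = "[AT]", S = "[CG]",
             R = "[AG]", Y = "[CT]", K = "[GT]", M = "[AC]", N = "[ACGT]")
    paste(vapply(.as_bases(toupper(pattern)), function(ch) {
        if (is.na(map[ch])) stop("unsupported motif character: ", ch)
        map[[ch]]
    }, ""), collapse = "")
}

# all (possibly overlapping) match start positions of regex `pat` in `x`
.match_starts <- function(x, pat) {
    m <- gregexpr(paste0("(?=", pat, ")"), x, perl = TRUE)[[1L]]
    if (m[1L] == -1L) integer() else as.integer(m)
}

# the `window` nucleotides immediately upstream of an ORF's ATG, on its coding
# strand, last character adjacent to the A of ATG.  Truncated (with a warning
# when window exceeds the genome) for linear genomes.
upstream_window <- function(genome, orf, window = 180L) {
    L <- genome$length
    if (window > L) {
        warning("window (", window, " nt) larger than genome; truncated to ", L)
        window <- L
    }
    if (window == 0L) return("")
    atg_pos <- if (orf$strand == "+") orf$start else orf$end
    if (genome$circular) {
        seq <- genome$sequence
        if (orf$strand == "+") {
            lo <- atg_pos - window
            s <- if (lo >= 1L) substring(seq, lo, atg_pos - 1L)
                 else paste0(substring(seq, L + lo, L),
                             if (atg_pos > 1L) substring(seq, 1L, atg_pos - 1L) else "")
            s
        } else {
            hi <- atg_pos + window
            s <- if (hi <= L) substring(seq, atg_pos + 1L, hi)
                 else paste0(if (atg_pos < L) substring(seq, atg_pos + 1L, L) else "",
                             substring(seq, 1L, hi - L))
            revcomp(s)
        }
    } else {
        if (orf$strand == "+") {
            lo <- max(1L, atg_pos - window)
            if (atg_pos <= 1L) return("")
            substring(genome$sequence, lo, atg_pos - 1L)
        } else {
            hi <- min(L, atg_pos + window)
            if (atg_pos >= L) return("")
            revcomp(substring(genome$sequence, atg_pos + 1L, hi))
        }
    }
}

#' Find early promoter motif pairs upstream of an ORF
#'
#' @param genome a \code{\link{circular_genome}}.
#' @param orf one ORF record (row of an annotation's \code{orfs} table).
#' @param window upstream scan window in nt (default 180).
#' @param spacer_min,spacer_max allowed distance, in nt, from the first base
#'   of the TATA box to the first base of the initiator (defaults 20 and 40).
#' @param tata_pattern the TATA-box motif; literal by default ("TATA"), simple
#'   IUPAC codes accepted (e.g. "TATAWA").
#' @return data frame with one row per (TATA, initiator) pair: offsets of each
#'   motif's first base upstream of the A of ATG (1 = immediately adjacent),
#'   matched sequences, and the spacer length.
#' @export
find_early_motifs <- function(genome, orf, window = 180L,
                              spacer_min = 20L, spacer_max = 40L,
                              tata_pattern = "TATA") {
    w <- upstream_window(genome, orf, window)
    W <- nchar(w)
    empty <- data.frame(tata_offset = integer(), initiator_offset = integer(),
                        tata_seq = character(), initiator_seq = character(),
                        spacer = integer())
    if (W == 0L) return(empty)
    tlen <- nchar(tata_pattern)
    tata_p <- .match_starts(w, .iupac_regex(tata_pattern))
    init_p <- .match_starts(w, "CA[GT]T")
    if (!length(tata_p) || !length(init_p)) return(empty)
    rows <- list()
    for (tp in tata_p) {
        for (ip in init_p) {
            spacer <- ip - tp
            if (spacer >= spacer_min && spacer <= spacer_max) {
                rows[[length(rows) + 1L]] <- data.frame(
                    tata_offset = W - tp + 1L, initiator_offset = W - ip + 1L,
                    tata_seq = substring(w, tp, tp + tlen - 1L),
                    initiator_seq = substring(w, ip, ip + 3L),
                    spacer = spacer)
            }
        }
    }
    if (!length(rows)) return(empty)
    do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Find late promoter motifs upstream of an ORF
#'
#' Every occurrence of ATAAG, TTAAG or GTAAG lying wholly within the upstream
#' window, on the ORF's coding strand.
#'
#' @inheritParams find_early_motifs
#' @return data frame with columns \code{offset} (first base, nt upstream of
#'   the A of ATG) and \code{matched_sequence}.
#' @export
find_late_motifs <- function(genome, orf, window = 180L) {
    w <- upstream_window(genome, orf, window)
    W <- nchar(w)
    p <- if (W > 0L) .match_starts(w, "[ATG]TAAG") else integer()
    if (!length(p)) {
        return(data.frame(offset = integer(), matched_sequence = character()))
    }
    data.frame(offset = W - p + 1L, matched_sequence = substring(w, p, p + 4L))
}

#' Classify promoters for every ORF of an annotation set
#'
#' An ORF is classified \code{both} if it has at least one early (TATA +
#' initiator) pair and at least one late motif, \code{early} / \code{late}
#' if only one kind is present, and \code{none} otherwise.
#'
#' @param genome a \code{\link{circular_genome}}.
#' @param ann an \code{\link{annotation_set}} for the same genome.
#' @inheritParams find_early_motifs
#' @return a list with \code{ann} (the annotation set with
#'   \code{promoter_class} filled in) and \code{tally}, a named integer vector
#'   \code{c(early_only, late_only, both, none)} summing to the ORF count.
#' @export
classify_promoters <- function(genome, ann, window = 180L,
                               spacer_min = 20L, spacer_max = 40L,
                               tata_pattern = "TATA") {
    stopifnot(inherits(ann, "annotation_set"))
    orfs <- ann$orfs
    cls <- character(nrow(orfs))
    for (i in seq_len(nrow(orfs))) {
        orf <- orfs[i, ]
        has_early <- nrow(find_early_motifs(genome, orf, window, spacer_min,
                                            spacer_max, tata_pattern)) > 0L
        has_late <- nrow(find_late_motifs(genome, orf, window)) > 0L
        cls[i] <- if (has_early && has_late) "both"
                  else if (has_early) "early"
                  else if (has_late) "late"
                  else "none"
    }
    orfs$promoter_class <- cls
    ann$orfs <- orfs
    tally <- c(early_only = sum(cls == "early"), late_only = sum(cls == "late"),
               both = sum(cls == "both"), none = sum(cls == "none"))
    list(ann = ann, tally = tally)
}

#' Tally promoter classes of an annotation set
#'
#' @param ann an \code{\link{annotation_set}}.
#' @return named integer vector \code{c(early_only, late_only, both, none)};
#'   \code{unassigned} ORFs are counted under \code{none}.
#' @export
promoter_tally <- function(ann) {
    cls <- ann$orfs$promoter_class
    c(early_only = sum(cls == "early"), late_only = sum(cls == "late"),
      both = sum(cls == "both"), none = sum(cls %in% c("none", "unassigned")))
}
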