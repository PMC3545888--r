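# Seeded synthetic-genome generator with full ground truth.
#
# Construction invariant: outside planted features the emitted sequence never
# contains the dinucleotide "AT".  Since both start-codon spellings (ATG on
# the plus strand, CAT as the plus-strand image of a reverse-strand ATG)
# contain "AT", the only start codons in the genome are the planted ones, so
# ORF recovery is exact by construction rather than merely probable.  Gene
# bodies are drawn from the codon alphabet without "AT" (which also excludes
# internal Met and all Ile codons - a documented restriction of the
# generator), spacers from a stop-rich token alphabet without "AT", and
# planted motifs / repeat units are audited for the same invariant.

# spacer token alphabet: plus- and minus-strand stop codons plus fillers,
# none containing "AT"
.SPACER_TOKENS <- c("TAA", "TGA", "TAG", "TTA", "CTA", "TCA",
                    "GGC", "CCG", "GCC", "CGG", "GAG", "CTC")
.SPACER_W <- c(2, 2, 2, 2, 2, 2, 1, 1, 1, 1, 1, 1)

.body_codons <- local({
    b <- c("A", "C", "G", "T")
    all3 <- as.vector(outer(outer(b, b, paste0), b, paste0))
    all3[!grepl("AT", all3, fixed = TRUE) & !(all3 %in% c("TAA", "TAG", "TGA"))]
})

# stream of spacer tokens of total length >= n, trimmed to n, never starting
# with 'T' after a preceding 'A'
.token_stream <- function(n, prev_char = "G") {
    if (n <= 0L) return(character())
    out <- character(0L)
    len <- 0L
    last <- prev_char
    while (len < n) {
        repeat {
            tok <- sample(.SPACER_TOKENS, 1L, prob = .SPACER_W)
            if (!(last == "A" && substring(tok, 1L, 1L) == "T")) break
        }
        out <- c(out, tok)
        len <- len + nchar(tok)
        last <- substring(tok, 3L, 3L)
    }
    v <- .as_bases(paste(out, collapse = ""))[seq_len(n)]
    v
}

# random gene of len_aa amino acids from the restricted codon alphabet;
# returns list(seq, protein)
.make_gene <- function(len_aa) {
    stopifnot(len_aa >= 2L)
    body <- character(len_aa - 1L)
    last <- "G"                               # ATG ends in G
    for (k in seq_len(len_aa - 1L)) {
        pool <- .body_codons
        if (last == "A") pool <- pool[substring(pool, 1L, 1L) != "T"]
        if (k == len_aa - 1L) pool <- pool[substring(pool, 3L, 3L) != "A"]
        body[k] <- sample(pool, 1L)
        last <- substring(body[k], 3L, 3L)
    }
    codons <- c("ATG", body)
    list(seq = paste(c(codons, "TAA"), collapse = ""),
         protein = paste(unname(Biostrings::GENETIC_CODE[codons]), collapse = ""))
}

# mutate position pos of char vector v to a random different base that does
# not create an "AT" dinucleotide with its neighbours; returns v
.mutate_safe <- function(v, pos) {
    cand <- sample(setdiff(c("A", "C", "G", "T"), v[pos]))
    for (ch in cand) {
        left <- if (pos > 1L) v[pos - 1L] else ""
        right <- if (pos < length(v)) v[pos + 1L] else ""
        if (left == "A" && ch == "T") next
        if (ch == "A" && right == "T") next
        v[pos] <- ch
        return(v)
    }
    v                                          # no safe change; leave as is
}

# -- promoter-window construction ------------------------------------------

.find_motif_hits <- function(w) {
    s <- paste(w, collapse = "")
    list(tata = .match_starts(s, "TATA"),
         init = .match_starts(s, "CA[GT]T"),
         late = .match_starts(s, "[ATG]TAAG"))
}

# build a 180-nt window (coding orientation, last char adjacent to the ATG)
# carrying exactly the motifs of `class`
.make_window <- function(class, window = 180L) {
    w <- .token_stream(window)
    protected <- integer(0L)
    splice <- function(w, motif, pos) {
        m <- .as_bases(motif)
        w[pos:(pos + length(m) - 1L)] <- m
        # repair possible "AT" hazards at the motif edges (replacement chars
        # C/G cannot create new "AT")
        if (pos > 1L && w[pos - 1L] == "A" && m[1L] == "T") w[pos - 1L] <- "C"
        p2 <- pos + length(m)
        if (p2 <= length(w) && m[length(m)] == "A" && w[p2] == "T") w[p2] <- "C"
        w
    }
    planted <- list()
    if (class %in% c("early", "both")) {
        o_t <- sample(60:170, 1L)              # TATA first-base offset
        spc <- sample(20:40, 1L)
        o_i <- o_t - spc                       # initiator first-base offset
        p_t <- window - o_t + 1L
        p_i <- window - o_i + 1L
        w <- splice(w, "TATA", p_t)
        w <- splice(w, "CAGT", p_i)
        planted$tata <- p_t; planted$init <- p_i
        protected <- c(protected, p_t:(p_t + 3L), p_i:(p_i + 3L))
    }
    if (class %in% c("late", "both")) {
        repeat {
            o_l <- sample(10:170, 1L)
            p_l <- window - o_l + 1L
            if (!any((p_l:(p_l + 4L)) %in% protected)) break
        }
        w <- splice(w, "GTAAG", p_l)
        planted$late <- p_l
        protected <- c(protected, p_l:(p_l + 4L))
    }
    scrub_tata <- class %in% c("late", "none")
    scrub_late <- class %in% c("early", "none")
    for (iter in 1:100) {
        if (w[window] == "C") w[window] <- "G"  # keep the gene junction inert
        hits <- .find_motif_hits(w)
        bad <- integer(0L); bad_len <- integer(0L)
        if (scrub_tata && length(hits$tata)) { bad <- c(bad, hits$tata); bad_len <- c(bad_len, rep(4L, length(hits$tata))) }
        if (scrub_late) {
            hl <- setdiff(hits$late, planted$late %||% integer(0L))
            if (length(hl)) { bad <- c(bad, hl); bad_len <- c(bad_len, rep(5L, length(hl))) }
        }
        if (!length(bad)) break
        p <- bad[1L]; len <- bad_len[1L]
        fixed <- FALSE
        for (off in c(1L, 2L, 0L, 3L)) {
            pos <- p + off
            if (pos > length(w) || pos %in% protected) next
            for (ch in c("C", "G")) {
                if (ch == w[pos]) next
                left <- if (pos > 1L) w[pos - 1L] else ""
                if (left == "C" && ch == "A") next   # never approach CAT
                w[pos] <- ch
                fixed <- TRUE
                break
            }
            if (fixed) break
        }
        if (!fixed) stop("window scrub failed to converge")
    }
    hits <- .find_motif_hits(w)
    if (scrub_tata && length(hits$tata)) stop("window scrub left a TATA box")
    if (scrub_late && length(setdiff(hits$late, planted$late %||% integer(0L)))) {
        stop("window scrub left a late motif")
    }
    w
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# -- hr cassette construction ----------------------------------------------

# AT-biased base sampler avoiding an "AT" dinucleotide after `prev`
.biased_base <- function(prev, at_bias) {
    p <- c(A = at_bias / 2, T = at_bias / 2,
           C = (1 - at_bias) / 2, G = (1 - at_bias) / 2)
    if (prev == "A") p["T"] <- 0
    sample(names(p), 1L, prob = p)
}

.biased_string <- function(n, at_bias, prev = "G", last_not = character()) {
    v <- character(n)
    for (i in seq_len(n)) {
        repeat {
            ch <- .biased_base(prev, at_bias)
            if (i == n && ch %in% last_not) next
            break
        }
        v[i] <- ch
        prev <- ch
    }
    v
}

# perfect palindrome of length len (even): arm + its reverse complement,
# arm never ending in A (the centre would otherwise read "AT")
.make_palindrome <- function(len, at_bias) {
    arm <- .biased_string(len %/% 2L, at_bias, last_not = "A")
    # centre junction: arm_last + comp(arm_last); comp can't be T unless arm
    # ends in A, which is excluded
    paste0(paste(arm, collapse = ""),
           revcomp(paste(arm, collapse = "")))
}

# -- the generator ----------------------------------------------------------

#' Generator configuration
#'
#' Bundles every tunable of the synthetic-genome, divergence and qPCR
#' simulators, with defaults emulating the structures of an annotated NPV
#' genome: ~40-bp near-palindromic hr units with 31-bp flanks, a multi-gene
#' segmental deletion in the diverged partner, and four-phase replication
#' kinetics (drop to 4 h, flat to 12 h, exponential 12-48 h with the
#' published endpoint values 452 and 2.02e11 per 1e5 actin, slow rise to
#' 1.17e12 at 96 h).
#'
#' @param seed RNG seed (the generator is byte-deterministic given the
#'   configuration).
#' @param n_orfs number of planted ORFs.
#' @param orf_length_range protein length range in aa.
#' @param promoter_mix named fractions (early, late, both, none) summing to 1.
#' @param n_hr_cassettes number of planted hr cassettes.
#' @param units_per_hr_range range of type-A (palindrome) units per cassette;
#'   type-B flanks are interleaved around them.
#' @param palindrome_len,flank_len unit lengths (40 / 31 nt).
#' @param at_bias_in_hr AT fraction targeted inside hr units.
#' @param hr_unit_noise substitutions planted per repeat unit.
#' @param divergence per-nucleotide substitution rate for
#'   \code{\link{diverge_genome}}.
#' @param deletion_block c(first gene index, number of genes) removed in the
#'   diverged partner.
#' @param relocated_gene gene index moved to a new locus in the partner (NA
#'   for none).
#' @param genome_length total length; NULL (default) sizes the genome to its
#'   contents.  An explicit value smaller than required is an error.
#' @param window upstream promoter window (matches the scanner default).
#' @param qpcr list of kinetics parameters; see
#'   \code{\link{simulate_qpcr_experiment}}.
#' @return a list of class \code{generator_config}.
#' @export
generator_config <- function(seed = 1L, n_orfs = 20L,
                             orf_length_range = c(60L, 180L),
                             promoter_mix = c(early = 0.25, late = 0.25,
                                              both = 0.25, none = 0.25),
                             n_hr_cassettes = 4L,
                             units_per_hr_range = c(3L, 7L),
                             palindrome_len = 40L, flank_len = 31L,
                             at_bias_in_hr = 0.7, hr_unit_noise = 1L,
                             divergence = 0.05,
                             deletion_block = c(10L, 5L),
                             relocated_gene = NA_integer_,
                             genome_length = NULL,
                             window = 180L,
                             qpcr = list()) {
    stopifnot(abs(sum(promoter_mix) - 1) < 1e-9,
              all(promoter_mix >= 0), divergence >= 0, divergence <= 1,
              palindrome_len %% 2L == 0L)
    qd <- list(times = c(0, 4, 8, 12, 24, 36, 48, 72, 96),
               init_value = 1808,             # normalised copies at t = 0
               drop_factor = 4,               # decrease over the 0-4 h phase
               latent_end_h = 12,
               expo_rate_log2_per_h = log2(2.02e11 / 452) / 36,
               expo_end_h = 48,
               stationary_rate_log2_per_h = log2(1.17e12 / 2.02e11) / 48,
               actin_copies = 2e5,
               slope = -1 / log10(2), intercept_viral = 38,
               intercept_actin = 36,
               standards_log10 = 1:8,
               ct_noise_sd = 0.3)
    qd[names(qpcr)] <- qpcr
    structure(list(seed = as.integer(seed), n_orfs = as.integer(n_orfs),
                   orf_length_range = orf_length_range,
                   promoter_mix = promoter_mix,
                   n_hr_cassettes = as.integer(n_hr_cassettes),
                   units_per_hr_range = units_per_hr_range,
                   palindrome_len = as.integer(palindrome_len),
                   flank_len = as.integer(flank_len),
                   at_bias_in_hr = at_bias_in_hr,
                   hr_unit_noise = as.integer(hr_unit_noise),
                   divergence = divergence, deletion_block = deletion_block,
                   relocated_gene = relocated_gene,
                   genome_length = genome_length, window = as.integer(window),
                   qpcr = qd),
              class = "generator_config")
}

# block-list builder with junction repair; blocks are lists with fields
# kind/seq plus free metadata
.new_builder <- function() {
    env <- new.env(parent = emptyenv())
    env$blocks <- list()
    env$last <- "G"
    env
}

.builder_add <- function(bd, seq, kind, ...) {
    first2 <- substring(seq, 1L, 2L)
    first1 <- substring(seq, 1L, 1L)
    if (bd$last == "A" && first1 == "T") {
        bd$blocks[[length(bd$blocks) + 1L]] <- list(kind = "fill", seq = "C")
        bd$last <- "C"
    }
    if (bd$last == "C" && first2 == "AT") {
        bd$blocks[[length(bd$blocks) + 1L]] <- list(kind = "fill", seq = "G")
        bd$last <- "G"
    }
    bd$blocks[[length(bd$blocks) + 1L]] <- c(list(kind = kind, seq = seq), list(...))
    bd$last <- substring(seq, nchar(seq), nchar(seq))
    invisible(bd)
}

# concatenate a block list into a sequence, assigning start/end coordinates
.assemble_blocks <- function(blocks) {
    pos <- 1L
    for (i in seq_along(blocks)) {
        n <- nchar(blocks[[i]]$seq)
        blocks[[i]]$start <- pos
        blocks[[i]]$end <- pos + n - 1L
        pos <- pos + n
    }
    list(blocks = blocks, sequence = paste(vapply(blocks, `[[`, "", "seq"),
                                           collapse = ""))
}

#' Generate an annotated synthetic genome with ground truth
#'
#' Plants \code{n_orfs} ORFs (random codons over an alphabet that cannot
#' create spurious start codons, stop-rich intergenic spacers), a promoter
#' window of the configured class immediately upstream of every ORF (spurious
#' motifs scrubbed from windows that must lack them), and
#' \code{n_hr_cassettes} hr cassettes of alternating type-B / type-A units
#' with AT bias and per-unit noise.  Deterministic given the configuration.
#'
#' @param cfg a \code{\link{generator_config}}.
#' @return list with \code{genome} (a \code{\link{circular_genome}}) and
#'   \code{truth}: \code{orfs} (coordinates, strand, class, protein),
#'   \code{hr_regions}, \code{hr_units}, \code{blocks} (internal layout used
#'   by \code{\link{diverge_genome}}), \code{config}.
#' @export
generate_annotated_genome <- function(cfg) {
    stopifnot(inherits(cfg, "generator_config"))
    set.seed(cfg$seed)
    n <- cfg$n_orfs
    classes <- character(0L)
    if (n > 0L) {
        counts <- floor(cfg$promoter_mix * n)
        rem <- n - sum(counts)
        if (rem > 0L) {
            extra <- order(cfg$promoter_mix * n - counts, decreasing = TRUE)[seq_len(rem)]
            counts[extra] <- counts[extra] + 1L
        }
        classes <- sample(rep(names(cfg$promoter_mix), counts))
    }
    strands <- if (n > 0L) sample(c("+", "-"), n, replace = TRUE) else character()
    lens <- if (n > 0L) sample(cfg$orf_length_range[1L]:cfg$orf_length_range[2L],
                               n, replace = TRUE) else integer()
    hr_gaps <- if (cfg$n_hr_cassettes > 0L && n > 1L) {
        sort(sample(seq_len(n - 1L), min(cfg$n_hr_cassettes, n - 1L)))
    } else integer()

    # one genome-wide B consensus and palindrome template, as in real hrs,
    # where the repeat units of all regions are variants of shared motifs
    b_cons <- paste(.biased_string(cfg$flank_len, cfg$at_bias_in_hr), collapse = "")
    pal <- .make_palindrome(cfg$palindrome_len, cfg$at_bias_in_hr)
    noisy <- function(s) {
        v <- .as_bases(s)
        if (cfg$hr_unit_noise > 0L) {
            for (p in sample(seq_along(v), min(cfg$hr_unit_noise, length(v)))) {
                v <- .mutate_safe(v, p)
            }
        }
        paste(v, collapse = "")
    }

    bd <- .new_builder()
    .builder_add(bd, paste(c("C", "C", .token_stream(58L, "C")), collapse = ""), "spacer")
    for (i in seq_len(n)) {
        if (strands[i] == "+") {
            w <- .make_window(classes[i], cfg$window)
            .builder_add(bd, paste(w, collapse = ""), "window", gene = i)
            g <- .make_gene(lens[i])
            .builder_add(bd, g$seq, "gene", gene = i, strand = "+",
                         class = classes[i], protein = g$protein)
        } else {
            g <- .make_gene(lens[i])
            .builder_add(bd, revcomp(g$seq), "gene", gene = i, strand = "-",
                         class = classes[i], protein = g$protein)
            w <- .make_window(classes[i], cfg$window)
            .builder_add(bd, revcomp(paste(w, collapse = "")), "window", gene = i)
        }
        if (i %in% hr_gaps) {
            .builder_add(bd, paste(.token_stream(60L, bd$last), collapse = ""), "spacer")
            hr_id <- match(i, hr_gaps)
            n_a <- sample(cfg$units_per_hr_range[1L]:cfg$units_per_hr_range[2L], 1L)
            for (u in seq_len(n_a)) {
                .builder_add(bd, noisy(b_cons), "hr_unit", hr = hr_id, unit_type = "B")
                .builder_add(bd, paste(.token_stream(sample(6:15, 1L), bd$last),
                                       collapse = ""), "hr_gap", hr = hr_id)
                .builder_add(bd, noisy(pal), "hr_unit", hr = hr_id, unit_type = "A")
                .builder_add(bd, paste(.token_stream(sample(6:15, 1L), bd$last),
                                       collapse = ""), "hr_gap", hr = hr_id)
            }
            .builder_add(bd, noisy(b_cons), "hr_unit", hr = hr_id, unit_type = "B")
            .builder_add(bd, paste(.token_stream(60L, bd$last), collapse = ""), "spacer")
        } else {
            .builder_add(bd, paste(.token_stream(60L, bd$last), collapse = ""), "spacer")
        }
    }
    built_len <- sum(vapply(bd$blocks, function(b) nchar(b$seq), 0L))
    tail_len <- if (is.null(cfg$genome_length)) 300L else cfg$genome_length - built_len - 2L
    if (tail_len < 2L) {
        stop("infeasible packing: contents need ", built_len + 4L,
             " nt but genome_length is ", cfg$genome_length)
    }
    .builder_add(bd, paste(c(.token_stream(tail_len, bd$last), "G", "G"),
                           collapse = ""), "spacer")
    asm <- .assemble_blocks(bd$blocks)
    genome <- circular_genome(paste0("synthetic_seed", cfg$seed), asm$sequence)

    blocks <- asm$blocks
    is_gene <- vapply(blocks, function(b) b$kind == "gene", TRUE)
    gb <- blocks[is_gene]
    orfs <- data.frame(
        index = vapply(gb, `[[`, 0L, "gene"),
        start = vapply(gb, `[[`, 0L, "start"),
        end = vapply(gb, `[[`, 0L, "end"),
        strand = vapply(gb, `[[`, "", "strand"),
        length_aa = integer(length(gb)),
        promoter_class = vapply(gb, `[[`, "", "class"),
        protein = vapply(gb, `[[`, "", "protein"))
    orfs$length_aa <- nchar(orfs$protein)
    orfs <- orfs[order(orfs$index), , drop = FALSE]
    rownames(orfs) <- NULL
    is_unit <- vapply(blocks, function(b) b$kind == "hr_unit", TRUE)
    ub <- blocks[is_unit]
    hr_units <- if (length(ub)) data.frame(
        region = vapply(ub, `[[`, 0L, "hr"),
        unit_type = vapply(ub, `[[`, "", "unit_type"),
        start = vapply(ub, `[[`, 0L, "start"),
        end = vapply(ub, `[[`, 0L, "end"))
    else data.frame(region = integer(), unit_type = character(),
                    start = integer(), end = integer())
    hr_regions <- if (nrow(hr_units)) do.call(rbind, lapply(
        split(hr_units, hr_units$region), function(u) {
            data.frame(region = u$region[1L], start = min(u$start),
                       end = max(u$end), n_a = sum(u$unit_type == "A"),
                       n_b = sum(u$unit_type == "B"))
        }))
    else data.frame(region = integer(), start = integer(), end = integer(),
                    n_a = integer(), n_b = integer())
    rownames(hr_regions) <- NULL
    # construction self-check: the only start codons are the planted ones
    n_atg <- length(.match_starts(asm$sequence, "ATG"))
    n_cat <- length(.match_starts(asm$sequence, "CAT"))
    stopifnot(n_atg == sum(orfs$strand == "+"), n_cat == sum(orfs$strand == "-"))
    list(genome = genome,
         truth = list(orfs = orfs, hr_regions = hr_regions, hr_units = hr_units,
                      blocks = blocks, config = cfg))
}

# synonymous-biased codon mutation using the full genetic code
.mutate_codon <- function(codon) {
    gc <- Biostrings::GENETIC_CODE
    if (runif(1L) < 0.7) {
        syn <- names(gc)[gc == gc[[codon]]]
        syn <- setdiff(syn, codon)
        if (length(syn)) return(sample(syn, 1L))
    }
    pool <- setdiff(names(gc)[gc != "*"], codon)
    sample(pool, 1L)
}

#' Derive a diverged partner genome
#'
#' Applies point substitutions at the configured rate (synonymous-biased
#' inside ORFs; suppressed inside promoter windows and hr units so motif and
#' repeat tests stay orthogonal to divergence), removes one contiguous block
#' of genes (\code{deletion_block}), and optionally relocates one gene to a
#' new locus near the end of the genome.
#'
#' @param parent result of \code{\link{generate_annotated_genome}}.
#' @param cfg the same (or an adjusted) \code{\link{generator_config}}.
#' @return list with \code{genome}, \code{truth} (same shape as the parent
#'   truth), and \code{homology}: data frame \code{index_parent},
#'   \code{index_partner}, \code{aa_identity_true} (percent).
#' @export
diverge_genome <- function(parent, cfg = parent$truth$config) {
    set.seed(cfg$seed + 104729L)              # distinct stream from the parent
    blocks <- parent$truth$blocks
    n <- nrow(parent$truth$orfs)
    del <- cfg$deletion_block
    deleted <- integer(0L)
    if (!is.null(del) && length(del) == 2L && !is.na(del[1L]) && del[2L] > 0L) {
        if (del[1L] <= 1L || del[1L] + del[2L] - 1L >= n) {
            stop("deletion_block out of range: must leave a flanking gene on each side")
        }
        deleted <- seq.int(del[1L], del[1L] + del[2L] - 1L)
    }
    reloc <- cfg$relocated_gene
    if (!is.na(reloc) && (reloc %in% deleted || reloc < 1L || reloc > n)) {
        stop("relocated_gene out of range or inside the deletion block")
    }
    gene_of <- vapply(blocks, function(b) b$gene %||% NA_integer_, 0L)
    drop_idx <- which(!is.na(gene_of) & gene_of %in% deleted)
    if (length(drop_idx)) blocks <- blocks[-seq.int(min(drop_idx), max(drop_idx))]
    gene_of <- vapply(blocks, function(b) b$gene %||% NA_integer_, 0L)
    if (!is.na(reloc)) {
        take <- which(!is.na(gene_of) & gene_of == reloc)
        take <- seq.int(min(take), max(take))
        moved <- blocks[take]
        blocks <- blocks[-take]
        tail_at <- length(blocks)             # insert before the tail spacer
        blocks <- c(blocks[seq_len(tail_at - 1L)],
                    list(list(kind = "spacer",
                              seq = paste(.token_stream(60L), collapse = ""))),
                    moved,
                    list(list(kind = "spacer",
                              seq = paste(.token_stream(60L), collapse = ""))),
                    blocks[tail_at])
    }
    d <- cfg$divergence
    mut <- function(b) {
        if (d == 0) return(b)
        if (b$kind %in% c("window", "hr_unit", "fill")) return(b)  # suppressed
        if (b$kind == "gene") {
            s <- if (b$strand == "-") revcomp(b$seq) else b$seq
            ncod <- nchar(s) %/% 3L
            codons <- substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
            hit <- which(runif(ncod - 2L) < 1 - (1 - d)^3) + 1L  # body codons only
            for (k in hit) codons[k] <- .mutate_codon(codons[k])
            s <- paste(codons, collapse = "")
            b$seq <- if (b$strand == "-") revcomp(s) else s
            b$protein <- paste(unname(Biostrings::GENETIC_CODE[codons[-length(codons)]]),
                               collapse = "")
        } else {
            v <- .as_bases(b$seq)
            hit <- which(runif(length(v)) < d)
            for (p in hit) {
                v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1L)
            }
            b$seq <- paste(v, collapse = "")
        }
        b
    }
    blocks <- lapply(blocks, mut)
    # reassemble through a fresh builder so cut junctions are repaired
    bd <- .new_builder()
    for (b in blocks) {
        meta <- b[setdiff(names(b), c("kind", "seq", "start", "end"))]
        do.call(.builder_add, c(list(bd, b$seq, b$kind), meta))
    }
    asm <- .assemble_blocks(bd$blocks)
    genome <- circular_genome(paste0(parent$genome$id, "_partner"), asm$sequence)
    blocks2 <- asm$blocks
    gb <- blocks2[vapply(blocks2, function(b) b$kind == "gene", TRUE)]
    orfs <- data.frame(
        parent_index = vapply(gb, `[[`, 0L, "gene"),
        start = vapply(gb, `[[`, 0L, "start"),
        end = vapply(gb, `[[`, 0L, "end"),
        strand = vapply(gb, `[[`, "", "strand"),
        promoter_class = vapply(gb, `[[`, "", "class"),
        protein = vapply(gb, `[[`, "", "protein"))
    orfs <- orfs[order(orfs$start), , drop = FALSE]
    orfs$index <- seq_len(nrow(orfs))
    orfs$length_aa <- nchar(orfs$protein)
    rownames(orfs) <- NULL
    pa <- parent$truth$orfs
    m <- match(orfs$parent_index, pa$index)
    ident <- vapply(seq_len(nrow(orfs)), function(i) {
        a <- .as_bases(pa$protein[m[i]]); b <- .as_bases(orfs$protein[i])
        100 * mean(a == b)
    }, 0)
    homology <- data.frame(index_parent = orfs$parent_index,
                           index_partner = orfs$index,
                           aa_identity_true = ident)
    list(genome = genome,
         truth = list(orfs = orfs, blocks = blocks2, config = cfg),
         homology = homology)
}

#' Simulate a qPCR replication-kinetics experiment
#'
#' True normalised viral load follows a four-phase piecewise-log-linear
#' trajectory (decreasing, latent, exponential, stationary); viral and actin
#' copy numbers are converted to Ct values through configured standard
#' curves, Gaussian noise of sd \code{ct_noise_sd} is added, and triplicates
#' are emitted together with the dilution-standard tables.
#'
#' @param cfg a \code{\link{generator_config}}; the \code{qpcr} element holds
#'   the kinetics parameters.
#' @return list with \code{standards} (target, log10_copies, ct_1..ct_3),
#'   \code{samples} (time_h, target, ct_1..ct_3), and \code{truth}
#'   (time_h, viral_copies, actin_copies, normalized_true).
#' @export
simulate_qpcr_experiment <- function(cfg) {
    stopifnot(inherits(cfg, "generator_config"))
    q <- cfg$qpcr
    if (q$init_value <= 0) stop("init_copies must be positive")
    set.seed(cfg$seed + 15485863L)
    t <- q$times
    drop_rate <- -log2(q$drop_factor) / 4
    lv0 <- log2(q$init_value)
    lv <- function(tt) {
        if (tt <= 4) return(lv0 + drop_rate * tt)
        base <- lv0 + drop_rate * 4
        if (tt <= q$latent_end_h) return(base)
        if (tt <= q$expo_end_h) return(base + q$expo_rate_log2_per_h * (tt - q$latent_end_h))
        base + q$expo_rate_log2_per_h * (q$expo_end_h - q$latent_end_h) +
            q$stationary_rate_log2_per_h * (tt - q$expo_end_h)
    }
    norm_true <- 2^vapply(t, lv, 0)
    viral <- norm_true * q$actin_copies / 1e5
    actin <- rep(q$actin_copies, length(t))
    ct_of <- function(copies, intercept) intercept + q$slope * log10(copies)
    trip <- function(ct) ct + rnorm(3L, 0, q$ct_noise_sd)
    std_rows <- list()
    for (tg in c("rr2b", "actin")) {
        icpt <- if (tg == "rr2b") q$intercept_viral else q$intercept_actin
        for (lc in q$standards_log10) {
            r <- trip(icpt + q$slope * lc)
            std_rows[[length(std_rows) + 1L]] <- data.frame(
                target = tg, log10_copies = lc,
                ct_1 = r[1L], ct_2 = r[2L], ct_3 = r[3L])
        }
    }
    smp_rows <- list()
    for (i in seq_along(t)) {
        for (tg in c("rr2b", "actin")) {
            copies <- if (tg == "rr2b") viral[i] else actin[i]
            icpt <- if (tg == "rr2b") q$intercept_viral else q$intercept_actin
            r <- trip(ct_of(copies, icpt))
            smp_rows[[length(smp_rows) + 1L]] <- data.frame(
                time_h = t[i], target = tg,
                ct_1 = r[1L], ct_2 = r[2L], ct_3 = r[3L])
        }
    }
    list(standards = do.call(rbind, c(std_rows, make.row.names = FALSE)),
         samples = do.call(rbind, c(smp_rows, make.row.names = FALSE)),
         truth = data.frame(time_h = t, viral_copies = viral,
                            actin_copies = actin, normalized_true = norm_true))
}
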