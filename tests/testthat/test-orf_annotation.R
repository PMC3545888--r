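# helper: embed a gene (ATG + n non-stop codons + TAA) in stop-rich padding
.pad <- function(n) strrep("TAACTATAG", ceiling(n / 9))

test_that("candidate scan handles degenerate and boundary inputs", {
    expect_length(find_candidate_orfs(as_genome(strrep("A", 300)))$start, 0)

    # exactly 50 aa (ATG + 49 codons + TAA = 153 nt) is called; 49 aa is not
    body49 <- strrep("GGC", 49)
    gene <- paste0("ATG", body49, "TAA")
    seq <- paste0(.pad(90), gene, .pad(90))
    g <- as_genome(seq, circular = FALSE)
    cand <- find_candidate_orfs(g, min_aa = 50)
    expect_equal(nrow(cand), 1)
    expect_equal(cand$length_aa, 50)
    expect_equal(cand$end - cand$start + 1, 153)
    expect_equal(nrow(find_candidate_orfs(g, min_aa = 51)), 0)

    # candidates containing N in a codon are rejected
    seqN <- sub("GGCGGC", "GGNGGC", seq, fixed = TRUE)
    expect_equal(nrow(find_candidate_orfs(as_genome(seqN, circular = FALSE),
                                          min_aa = 50)), 0)
})

test_that("an ORF crossing the origin is found iff the genome is circular", {
    gene <- paste0("ATG", strrep("GGC", 60), "TAA")
    pad <- .pad(400)
    lin <- paste0(pad, gene, pad)
    # rotate so the gene straddles position 1
    cut <- nchar(pad) + 90
    rot <- paste0(substring(lin, cut + 1, nchar(lin)), substring(lin, 1, cut))
    g_circ <- as_genome(rot, circular = TRUE)
    g_lin <- as_genome(rot, circular = FALSE)
    cand <- find_candidate_orfs(g_circ, min_aa = 50)
    expect_equal(nrow(cand), 1)
    expect_true(cand$wrap)
    expect_equal(cand$length_aa, 61)
    expect_equal(nrow(find_candidate_orfs(g_lin, min_aa = 50)), 0)
    # the wrapped candidate agrees with scanning the unrotated linearisation
    ref <- find_candidate_orfs(as_genome(lin, circular = FALSE), min_aa = 50)
    expect_equal(cand$length_aa, ref$length_aa)
})

test_that("candidate scan matches the brute-force oracle on random sequences", {
    set.seed(42)
    for (rep in 1:60) {
        L <- sample(90:260, 1)
        circ <- rep %% 2 == 0
        s <- rand_dna(L)
        got <- find_candidate_orfs(as_genome(s, circular = circ), min_aa = 8)
        want <- oracle_orfs(s, circular = circ, min_aa = 8)
        expect_equal(orf_key(got), orf_key(want),
                     info = paste("seq rep", rep, "circ", circ))
    }
    # and one 2-kb case
    s <- rand_dna(2000)
    got <- find_candidate_orfs(as_genome(s), min_aa = 25)
    expect_equal(orf_key(got), orf_key(oracle_orfs(s, TRUE, min_aa = 25)))
})

test_that("minimal-overlap resolution keeps, nests and caps as specified", {
    mk <- function(start, end, aa, strand = "+") {
        data.frame(start = start, end = end, strand = strand, frame = 0,
                   length_aa = aa, wrap = FALSE)
    }
    # disjoint: both kept
    out <- resolve_minimal_overlap(rbind(mk(1, 153, 50), mk(200, 400, 66)),
                                   genome_length = 1000)
    expect_equal(nrow(out), 2)
    expect_equal(out$index, c(1, 2))
    # 60-aa candidate nested inside a 300-aa one: only the long survives
    out <- resolve_minimal_overlap(rbind(mk(1, 903, 300), mk(101, 283, 60)),
                                   genome_length = 2000)
    expect_equal(nrow(out), 1)
    expect_equal(out$length_aa, 300)
    # 47-nt overlap (as retained in the HearMNPV table): both kept
    out <- resolve_minimal_overlap(rbind(mk(1, 300, 99), mk(254, 556, 100)),
                                   genome_length = 2000)
    expect_equal(nrow(out), 2)
    # overlap above the cap: the shorter one dropped
    out <- resolve_minimal_overlap(rbind(mk(1, 600, 199), mk(300, 899, 199)),
                                   max_overlap_nt = 250, genome_length = 2000)
    expect_equal(nrow(out), 1)
})

test_that("resolution is deterministic and independent of input order", {
    set.seed(11)
    s <- rand_dna(1500)
    cand <- find_candidate_orfs(as_genome(s), min_aa = 10)
    perm <- cand[sample(nrow(cand)), ]
    attr(perm, "genome_length") <- attr(cand, "genome_length")
    expect_equal(resolve_minimal_overlap(cand, 100),
                 resolve_minimal_overlap(perm, 100, genome_length = 1500))
})

test_that("translation covers both strands, wraps, and error paths", {
    g <- as_genome("ATGAAATAAGGG", circular = FALSE)
    expect_equal(translate_orf(g, list(start = 1, end = 9, strand = "+")), "MK")
    # same codons encoded on the reverse strand
    g2 <- as_genome(paste0("GG", revcomp("ATGAAATAA"), "G"), circular = FALSE)
    expect_equal(translate_orf(g2, list(start = 3, end = 11, strand = "-")), "MK")
    expect_error(translate_orf(g, list(start = 1, end = 8, strand = "+")),
                 "divisible")
    # wrapped ORF translates across the origin
    gene <- paste0("ATG", strrep("GAC", 10), "TAA")
    rot <- paste0(substring(gene, 19), .pad(45), substring(gene, 1, 18))
    gw <- as_genome(rot, circular = TRUE)
    st <- nchar(rot) - 17
    expect_equal(translate_orf(gw, list(start = st, end = 18, strand = "+", wrap = TRUE)),
                 paste0("M", strrep("D", 10)))
})

test_that("every resolved ORF satisfies the candidate invariants on random genomes", {
    set.seed(99)
    for (rep in 1:10) {
        s <- rand_dna(1200)
        g <- as_genome(s)
        orfs <- resolve_minimal_overlap(find_candidate_orfs(g, min_aa = 10),
                                        genome_length = 1200)
        if (!nrow(orfs)) next
        span <- orf_span_nt(orfs$start, orfs$end, orfs$wrap, 1200)
        expect_equal(span, 3 * orfs$length_aa + 3)
        for (i in seq_len(nrow(orfs))) {
            p <- translate_orf(g, orfs[i, ])
            expect_match(p, "^M")
            expect_false(grepl("*", p, fixed = TRUE))
            expect_equal(nchar(p), orfs$length_aa[i])
        }
    }
})

test_that("planted ORFs are recovered with precision and recall 1", {
    for (seed in c(3, 17)) {
        cfg <- generator_config(seed = seed, n_orfs = 15)
        gt <- generate_annotated_genome(cfg)
        got <- resolve_minimal_overlap(find_candidate_orfs(gt$genome),
                                       genome_length = gt$genome$length)
        expect_equal(got$start, gt$truth$orfs$start)
        expect_equal(got$end, gt$truth$orfs$end)
        expect_equal(got$strand, gt$truth$orfs$strand)
        pr <- vapply(seq_len(nrow(got)),
                     function(i) translate_orf(gt$genome, got[i, ]), "")
        expect_equal(pr, gt$truth$orfs$protein)
    }
})
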