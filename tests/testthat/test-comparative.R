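test_that("global alignment handles identity, hand-checkable and error cases", {
    a <- rand_prot(30)
    r <- align_global_identity(a, a)
    expect_equal(r$pct_identity, 100)
    expect_equal(r$identities, 30)
    expect_equal(r$aligned_length, 30)

    r <- align_global_identity("MKV", "MQV")
    expect_equal(r$identities, 2)
    expect_equal(r$aligned_length, 3)
    expect_equal(r$pct_identity, 200 / 3)

    expect_error(align_global_identity("MK1", "MK"), "non-amino-acid")
})

test_that("alignment score and identity are symmetric in the arguments", {
    set.seed(61)
    for (rep in 1:25) {
        a <- rand_prot(sample(5:40, 1)); b <- rand_prot(sample(5:40, 1))
        r1 <- align_global_identity(a, b)
        r2 <- align_global_identity(b, a)
        expect_equal(r1$score, r2$score)
        expect_equal(r1$pct_identity, r2$pct_identity)
    }
})

test_that("alignment score matches exhaustive enumeration on tiny instances", {
    set.seed(62)
    for (rep in 1:40) {
        a <- rand_prot(sample(2:7, 1)); b <- rand_prot(sample(2:7, 1))
        expect_equal(align_global_identity(a, b)$score,
                     oracle_align_score(a, b), info = paste(a, b))
    }
})

test_that("alignment score agrees with an independent aligner", {
    # Biostrings pairwiseAlignment under the equivalent scoring scheme
    set.seed(63)
    mat <- matrix(0, 26, 26, dimnames = list(LETTERS, LETTERS))
    diag(mat) <- 1
    for (rep in 1:20) {
        a <- rand_prot(sample(10:60, 1)); b <- rand_prot(sample(10:60, 1))
        ref <- Biostrings::pairwiseAlignment(a, b, substitutionMatrix = mat,
                                             gapOpening = 0, gapExtension = 1,
                                             type = "global", scoreOnly = TRUE)
        expect_equal(align_global_identity(a, b)$score, ref)
    }
})

test_that("reciprocal-best-hit mapping is exact on self and recovers divergence", {
    set.seed(64)
    prot <- vapply(1:8, function(i) rand_prot(sample(40:90, 1)), "")
    self <- map_homologs(prot, prot)
    expect_equal(nrow(self), 8)
    expect_equal(self$index_a, self$index_b)
    expect_true(all(self$pct_identity == 100))

    # an unpaired gene stays unpaired
    m <- map_homologs(prot, prot[-3])
    expect_false(3 %in% m$index_a)
    expect_equal(nrow(m), 7)
})

test_that("diverged proteome pairs are recovered from generator truth", {
    cfg <- generator_config(seed = 29, n_orfs = 14, divergence = 0.05,
                            deletion_block = c(5, 3))
    gt <- generate_annotated_genome(cfg)
    dv <- diverge_genome(gt)
    m <- map_homologs(gt$truth$orfs$protein, dv$truth$orfs$protein)
    truth <- dv$homology
    hit <- merge(m, truth, by.x = c("index_a", "index_b"),
                 by.y = c("index_parent", "index_partner"))
    expect_gte(nrow(hit) / nrow(truth), 0.98)
})

test_that("gene parity conserves ORFs and flags uniques", {
    pairs <- data.frame(index_a = c(1, 2, 4), index_b = c(1, 2, 3),
                        pct_identity = c(90, 40, 20))
    p <- gene_parity(pairs, n_a = 5, n_b = 4)
    expect_equal(nrow(p$points), 3)
    expect_equal(p$unique_a, c(3, 5))
    expect_equal(p$unique_b, 4)
    expect_equal(nrow(p$points) + length(p$unique_a), p$n_a)
    expect_equal(nrow(p$points) + length(p$unique_b), p$n_b)
    expect_equal(p$points$identity_bin, c(">=70", "30-50", "<30"))
    expect_error(gene_parity(data.frame(index_a = c(1, 1), index_b = c(1, 2),
                                        pct_identity = c(50, 50)), 3, 3),
                 "duplicate")
})

test_that("the fixture's MacoNPV-B columns give 161 parity points and one unique ORF", {
    ann <- hearmnpv_annotation()
    h <- ann$homologs[ann$homologs$virus == "MacoNPV-B", ]
    pairs <- data.frame(index_a = h$orf_index,
                        index_b = as.integer(sub("[a-z]$", "", h$homolog_orf)),
                        pct_identity = h$pct_identity)
    p <- gene_parity(pairs, n_a = 162, n_b = max(pairs$index_b))
    expect_equal(nrow(p$points), 161)
    expect_equal(p$unique_a, 139)
})

test_that("collinearity statistics behave at the extremes and match the formula", {
    pts <- function(ra, rb) gene_parity(
        data.frame(index_a = ra, index_b = rb, pct_identity = 50),
        n_a = max(ra), n_b = max(rb))
    s <- collinearity_stats(pts(1:10, 1:10))
    expect_equal(s$rank_correlation, 1)
    expect_equal(s$adjacency_preserved_fraction, 1)
    s <- collinearity_stats(pts(1:10, 10:1))
    expect_equal(s$rank_correlation, -1)
    set.seed(65)
    ra <- 1:100; rb <- sample(100)
    s <- collinearity_stats(pts(ra, rb))
    expect_equal(s$rank_correlation, oracle_spearman(ra, rb))
})

test_that("segmental indel detection finds planted runs and boundaries", {
    # identical gene orders: nothing reported
    pairs <- data.frame(index_a = 1:10, index_b = 1:10)
    expect_equal(nrow(detect_segmental_indels(pairs, 1:10, 1:10)), 0)
    # a 5-gene run absent from genome A, flanked on both sides
    pairs <- data.frame(index_a = 1:10, index_b = c(1:4, 10:15))
    out <- detect_segmental_indels(pairs, 1:10, 1:15)
    expect_equal(nrow(out), 1)
    expect_equal(out$genome, "B")
    expect_equal(out$n_orfs, 5)
    expect_equal(out$first_orf, 5)
    expect_equal(out$last_orf, 9)
    expect_equal(out$flank_left, "4")
    expect_equal(out$flank_right, "10")
    # run at the end of the genome: terminal flank marker
    pairs <- data.frame(index_a = 1:8, index_b = 1:8)
    out <- detect_segmental_indels(pairs, 1:8, 1:10)
    expect_equal(out$flank_right, "terminal")
    expect_equal(out$n_orfs, 2)
})

test_that("the planted multi-gene deletion is recovered end to end", {
    cfg <- generator_config(seed = 71, n_orfs = 14, divergence = 0.03,
                            deletion_block = c(6, 5))
    gt <- generate_annotated_genome(cfg)
    dv <- diverge_genome(gt)
    m <- map_homologs(gt$truth$orfs$protein, dv$truth$orfs$protein)
    out <- detect_segmental_indels(m, 1:14, seq_len(nrow(dv$truth$orfs)))
    del <- out[out$genome == "A", ]
    expect_equal(nrow(del), 1)
    expect_equal(del$first_orf, 6)
    expect_equal(del$last_orf, 10)
    expect_equal(del$n_orfs, 5)
    expect_equal(del$flank_left, "5")
    expect_equal(del$flank_right, "11")
})

test_that("transposon signatures: constructed element, exactness, oracle", {
    itr <- "GGTCCTAAGACCC"
    elem <- paste0("TTAA", itr, strrep("C", 50), revcomp(itr), "TTAA")
    set.seed(66)
    seq <- paste0(rand_dna(100), elem, rand_dna(100))
    g <- circular_genome("t", seq, circular = FALSE)
    hit <- scan_transposon_signature(g, 1, nchar(seq), itr_len = 13)
    expect_equal(nrow(hit), 1)
    expect_equal(hit$element_start, 105)
    expect_equal(hit$element_end, 104 + nchar(elem) - 8)
    expect_equal(hit$itr_seq, itr)
    expect_equal(hit$left_tsd_pos, 101)

    # one mismatched ITR base: not reported (ITRs must be perfect)
    rc_bad <- revcomp(itr)
    substr(rc_bad, 7, 7) <- "C"
    elem_bad <- paste0("TTAA", itr, strrep("C", 50), rc_bad, "TTAA")
    g2 <- circular_genome("t", paste0(rand_dna(100), elem_bad, rand_dna(100)),
                          circular = FALSE)
    expect_equal(nrow(scan_transposon_signature(g2, 1, g2$length, itr_len = 13)), 0)

    expect_error(scan_transposon_signature(g, 1, 100, itr_len = 3), "at least 4")
})

test_that("transposon scan matches exhaustive pair enumeration", {
    set.seed(67)
    for (rep in 1:30) {
        L <- sample(150:300, 1)
        s <- rand_dna(L, p = c(0.35, 0.15, 0.15, 0.35))
        g <- circular_genome("t", s, circular = FALSE)
        got <- scan_transposon_signature(g, 5, L - 5, itr_len = 4,
                                         tsd = "TTAA", max_span = 200)
        want <- oracle_transposon(s, 5, L - 5, 4, "TTAA", 200)
        got <- got[order(got$element_start, got$element_end), ]
        expect_equal(got$element_start, want$element_start, info = rep)
        expect_equal(got$element_end, want$element_end, info = rep)
    }
})

test_that("summary identities reproduce the shared-gene columns", {
    ann <- hearmnpv_annotation()
    s <- summary_identities(ann, "MacoNPV-B")
    expect_equal(s$n_shared, 161)
    expect_equal(s$mean_pct_identity, 98.5)
    expect_error(summary_identities(ann, "NoSuchVirus"), "available")
    # single-row table
    orfs <- data.frame(index = 1, name = "", start = 1, end = 303, strand = "+",
                       length_aa = 100, promoter_class = "none", wrap = FALSE)
    hom <- data.frame(orf_index = 1, virus = "V", homolog_orf = "7",
                      pct_identity = 50)
    a2 <- annotation_set("g", 1000, orfs, hom)
    expect_equal(summary_identities(a2, "V")$mean_pct_identity, 50.0)
})
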