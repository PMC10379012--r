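# Independent oracle: per-position prefix counting, written naively.
nd_oracle <- function(sequence) {
  chars <- strsplit(sequence, "")[[1]]
  sapply(seq_along(chars), function(i) {
    sum(chars[1:i] == chars[i]) / i
  })
}

test_that("encode_ncp reproduces the chemical-property truth table", {
  expect_equal(encode_ncp("A"), c(r = 1, h = 1, f = 1))
  expect_equal(encode_ncp("C"), c(r = 0, h = 0, f = 1))
  expect_equal(encode_ncp("G"), c(r = 1, h = 0, f = 0))
  expect_equal(encode_ncp("T"), c(r = 0, h = 1, f = 0))
  expect_error(encode_ncp("N"), "A/C/G/T")
})

test_that("encode_nd matches brute-force prefix counting", {
  expect_equal(encode_nd("AAAA"), c(1, 1, 1, 1))
  expect_equal(encode_nd("ACGT"), c(1, 0.5, 1 / 3, 0.25))
  expect_equal(encode_nd("AACA"), c(1, 1, 1 / 3, 0.75))
  expect_error(encode_nd(""), "empty")

  set.seed(11)
  for (i in 1:50) {
    s <- random_seq(sample(1:500, 1))
    expect_equal(encode_nd(s), nd_oracle(s), tolerance = 1e-12)
  }
})

test_that("encode_eiip substitutes the fixed pseudopotential table", {
  expect_identical(encode_eiip("TAGC"), c(0.1335, 0.1260, 0.0806, 0.1340))
  expect_identical(encode_eiip("AA"), c(0.1260, 0.1260))
  expect_error(encode_eiip(""), "empty")
  expect_error(encode_eiip("ACGX"), "non-ACGT")
})

test_that("fit_bpb matches direct column counting, with and without smoothing", {
  recs <- data.frame(id = paste0("r", 1:4),
                     sequence = c("AA", "AA", "CC", "CC"),
                     label = c(1L, 1L, 0L, 0L))
  m0 <- fit_bpb(recs, 2, pseudocount = 0)
  expect_equal(unname(m0$positive_profile[1, "A"]), 1)
  expect_equal(unname(m0$positive_profile[1, "C"]), 0)
  expect_equal(unname(m0$negative_profile[1, "C"]), 1)

  recs2 <- data.frame(id = paste0("r", 1:3),
                      sequence = c("AC", "GC", "TT"),
                      label = c(1L, 1L, 0L))
  m2 <- fit_bpb(recs2, 2, pseudocount = 0)
  expect_equal(unname(m2$positive_profile[1, "A"]), 0.5)
  expect_equal(unname(m2$positive_profile[1, "G"]), 0.5)
  expect_equal(unname(m2$positive_profile[2, "C"]), 1)

  # Laplace smoothing: single positive "A" gives (1+1)/(1+4)
  recs3 <- data.frame(id = c("p", "n"), sequence = c("A", "C"),
                      label = c(1L, 0L))
  m3 <- fit_bpb(recs3, 1, pseudocount = 1)
  expect_equal(unname(m3$positive_profile[1, "A"]), 2 / 5)
  expect_equal(unname(m3$positive_profile[1, "C"]), 1 / 5)

  expect_error(fit_bpb(recs[recs$label == 1, ], 2), "both classes")
  expect_error(fit_bpb(recs, 3), "length")
})

test_that("fit_bpb profiles row-normalize and agree with counting on random corpora", {
  set.seed(5)
  for (rep in 1:10) {
    L <- sample(3:12, 1)
    n_pos <- sample(3:20, 1); n_neg <- sample(3:20, 1)
    recs <- data.frame(
      id = paste0("r", 1:(n_pos + n_neg)),
      sequence = replicate(n_pos + n_neg, random_seq(L)),
      label = rep(c(1L, 0L), c(n_pos, n_neg)))
    m <- fit_bpb(recs, L, pseudocount = 0)
    expect_equal(unname(rowSums(m$positive_profile)), rep(1, L),
                 tolerance = 1e-12)
    expect_equal(unname(rowSums(m$negative_profile)), rep(1, L),
                 tolerance = 1e-12)
    # oracle: direct frequency of each base in each positive column
    pos_seqs <- recs$sequence[recs$label == 1L]
    i <- sample(L, 1)
    col <- substr(pos_seqs, i, i)
    for (b in c("A", "C", "G", "T")) {
      expect_equal(unname(m$positive_profile[i, b]), mean(col == b))
    }
  }
})

test_that("encode_bpb looks up fitted profiles; uniform model is constant", {
  recs <- data.frame(id = paste0("r", 1:4),
                     sequence = c("AA", "AA", "CC", "CC"),
                     label = c(1L, 1L, 0L, 0L))
  m0 <- fit_bpb(recs, 2, pseudocount = 0)
  expect_equal(unname(encode_bpb("AA", m0)), c(1, 1, 0, 0))
  expect_error(encode_bpb("AAA", m0), "length")

  uni <- m0
  uni$positive_profile[] <- 0.25
  uni$negative_profile[] <- 0.25
  expect_equal(unname(encode_bpb("GT", uni)), rep(0.25, 4))
})

test_that("encode_local concatenates blocks in fixed order with stable names", {
  expect_equal(encode_local("TA", parts = "EIIP"),
               c(EIIP_0 = 0.1335, EIIP_1 = 0.1260))
  expect_equal(unname(encode_local("A", parts = "NCP_ND")), c(1, 1, 1, 1))

  recs <- data.frame(id = c("p", "q", "n", "o"),
                     sequence = c("ACG", "GTA", "TTT", "CCA"),
                     label = c(1L, 1L, 0L, 0L))
  m <- fit_bpb(recs, 3)
  full <- encode_local("ACG", m)
  expect_length(full, 7 * 3)
  expect_equal(names(full)[1:4], paste0("NCPND_", 0:3))
  expect_equal(names(full)[13], "EIIP_0")
  expect_equal(names(full)[16], "BPB_0")
  # length contract for every combination of parts
  for (parts in list("NCP_ND", "EIIP", "BPB", c("NCP_ND", "EIIP"),
                     c("EIIP", "BPB"), c("NCP_ND", "EIIP", "BPB"))) {
    L <- 3
    want <- 4 * L * ("NCP_ND" %in% parts) + L * ("EIIP" %in% parts) +
      2 * L * ("BPB" %in% parts)
    expect_length(encode_local("ACG", m, parts), want)
  }
  expect_error(encode_local("ACG", m, character(0)))
  expect_error(encode_local("ACG", parts = "BPB"), "bpb_model")
})

test_that("encoding is strictly positional: swapping bases permutes blocks", {
  s1 <- "ACGTT"
  s2 <- "GCATT"  # positions 1 and 3 swapped
  e1 <- encode_local(s1, parts = "EIIP")
  e2 <- encode_local(s2, parts = "EIIP")
  expect_equal(unname(e1[c(3, 2, 1, 4, 5)]), unname(e2))
  # NCP sub-block (r,h,f) permutes likewise; nd is prefix-dependent so only
  # the pure chemical triples are compared
  n1 <- matrix(encode_local(s1, parts = "NCP_ND"), nrow = 4)
  n2 <- matrix(encode_local(s2, parts = "NCP_ND"), nrow = 4)
  expect_equal(n1[1:3, c(3, 2, 1, 4, 5)], n2[1:3, ])
})

test_that("BPB model JSON round-trip preserves profiles", {
  recs <- data.frame(id = c("p", "q", "n", "o"),
                     sequence = c("ACG", "GTA", "TTT", "CCA"),
                     label = c(1L, 1L, 0L, 0L))
  m <- fit_bpb(recs, 3, pseudocount = 0.5)
  tmp <- withr::local_tempfile(fileext = ".json")
  write_bpb(m, tmp)
  m2 <- read_bpb(tmp)
  expect_equal(unname(m2$positive_profile), unname(m$positive_profile))
  expect_equal(m2$pseudocount, 0.5)
  expect_equal(encode_bpb("ACG", m2), encode_bpb("ACG", m))
})
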