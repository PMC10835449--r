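test_that("CSC is the Pearson correlation of codon frequency with half-life", {
  hl <- c(1, 2, 3, 5, 8)
  m <- cbind(A = c(10, 12, 15, 18, 25), B = c(30, 25, 28, 22, 20),
             C = c(5, 5, 5, 5, 5))
  # frozen values from the direct Pearson formula on this toy matrix
  raw <- compute_csc(m, hl, normalize = FALSE)
  expect_equal(unname(raw["A"]), 0.9970075686, tolerance = 1e-9)
  expect_equal(unname(raw["B"]), -0.8958886656, tolerance = 1e-9)
  norm <- compute_csc(m, hl)
  expect_equal(unname(norm["A"]), 0.9952366569, tolerance = 1e-9)
  expect_equal(unname(norm["B"]), -0.9894801337, tolerance = 1e-9)

  # frequency exactly proportional to half-life -> CSC 1
  m2 <- cbind(X = 2 * hl, Y = 10 - hl)
  expect_equal(unname(compute_csc(m2, hl, normalize = FALSE)["X"]), 1)
  # constant raw frequency -> zero variance -> NA (normalization rescales a
  # constant column by varying row totals, so the raw matrix is the case)
  expect_true(is.na(raw["C"]))
  # an absent codon stays flagged after normalization too
  expect_true(is.na(compute_csc(cbind(A = hl, Z = rep(0, 5)), hl)["Z"]))
})

test_that("CSC rejects degenerate inputs", {
  expect_error(compute_csc(matrix(1:4, 2, 2), c(1, 2)), "3 transcripts")
  expect_error(compute_csc(matrix(1:9, 3, 3), c(2, 2, 2)), "non-constant")
})

test_that("tAI normalizes availability and is scale invariant", {
  # two codons decoded Watson-Crick only, copies {2, 1} -> tAI {1.0, 0.5};
  # GGC's Watson-Crick anticodon is GCC, GGG's is CCC; wobble partners for
  # those codons get no copies here.
  copies <- c(GCC = 2, CCC = 1)
  w <- compute_tai(copies)
  expect_equal(unname(w["GGC"]), 1.0)
  expect_equal(unname(w["GGG"]), 0.5)
  w2 <- compute_tai(copies * 7)
  expect_equal(w, w2)
  # codons without any decoding anticodon get the geometric-mean fill-in;
  # GCC also wobble-decodes GGT at (1 - 0.41), giving the third nonzero value
  expect_true("AAA" %in% attr(w, "substituted"))
  expect_equal(unname(w["GGT"]), 2 * (1 - 0.41) / 2)
  expect_equal(unname(w["AAA"]), exp(mean(log(c(1, 0.5, 0.59)))))
  expect_error(compute_tai(c(GCC = 0)), "zero")
  expect_error(compute_tai(c(GCC = -1)), "non-negative")
})

test_that("tAI equals a brute-force wobble-pairing enumeration on 61 codons", {
  set.seed(5)
  anticodons <- revcomp(codon_table()$sense_codons)
  copies <- stats::setNames(rpois(length(anticodons), 4), anticodons)
  w <- compute_tai(copies)

  # independent oracle: loop over all 64 anticodons, test base pairing
  # positionally (anticodon 5'->3' pairs the codon 3'->5'; wobble at the
  # anticodon's first base), then normalize and fill zeros.
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  s_pen <- c(WC = 0, GU = 0.41, IC = 0.28, IA = 0.9999, UG = 0.68)
  all_ac <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                              c("A","C","G","T")), 1, paste, collapse = "")
  W <- sapply(codon_table()$sense_codons, function(codon) {
    cb <- strsplit(codon, "")[[1]]
    total <- 0
    for (ac in all_ac) {
      ab <- strsplit(ac, "")[[1]]
      if (comp[ab[3]] != cb[1] || comp[ab[2]] != cb[2]) next
      s <- if (comp[ab[1]] == cb[3]) s_pen[["WC"]]
      else if (codon == "ATG") NA_real_  # Met: Watson-Crick only
      else if (cb[3] == "T" && ab[1] == "G") s_pen[["GU"]]
      else if (cb[3] == "C" && ab[1] == "A") s_pen[["IC"]]
      else if (cb[3] == "A" && ab[1] == "A") s_pen[["IA"]]
      else if (cb[3] == "G" && ab[1] == "T") s_pen[["UG"]]
      else NA_real_
      if (is.na(s)) next
      cp <- copies[ac]
      if (!is.na(cp)) total <- total + (1 - s) * cp
    }
    unname(total)
  })
  w_oracle <- W / max(W)
  zero <- w_oracle == 0
  if (any(zero)) w_oracle[zero] <- exp(mean(log(w_oracle[!zero])))
  expect_equal(unname(w[names(w_oracle)]), unname(w_oracle),
               tolerance = 1e-12)
})

test_that("delta metrics are antisymmetric with single-unit GC changes", {
  ds <- small_dataset()
  csc <- ds$metrics$csc
  tai <- ds$metrics$tai

  rec <- delta_metrics("CAT", "CAC", csc, tai)
  expect_equal(rec$delta_gc, 1)
  expect_equal(rec$degeneracy, 2)
  expect_equal(delta_metrics("CAG", "CAA", csc, tai)$delta_gc, -1)

  ch <- enumerate_synonymous_changes(codon_table())
  for (i in seq_len(nrow(ch))) {
    fwd <- delta_metrics(ch$ref_codon[i], ch$alt_codon[i], csc, tai)
    rev <- delta_metrics(ch$alt_codon[i], ch$ref_codon[i], csc, tai)
    expect_equal(fwd$delta_csc, -rev$delta_csc)
    expect_equal(fwd$delta_tai, -rev$delta_tai)
    expect_equal(fwd$delta_gc, -rev$delta_gc)
    expect_true(fwd$delta_gc %in% c(-1, 0, 1))
  }

  expect_error(delta_metrics("CAT", "CAG", csc, tai), "synonymous")
  expect_error(delta_metrics("CAT", "CGC", csc, tai), "exactly one")
})

test_that("optimality classification follows the sign of delta CSC", {
  expect_equal(classify_optimality(c(-0.1, 0.2, 0, NA)),
               c("reducing", "increasing", "neutral", "unclassified"))
  # both-negative CSC pairs (the histidine situation) are still classifiable
  csc <- c(CAT = -0.3, CAC = -0.1)
  tai <- c(CAT = 0.5, CAC = 1)
  expect_equal(delta_metrics("CAT", "CAC", csc, tai)$optimality,
               "increasing")
})

test_that("usage bias rescales the max-fraction excess to [0, 1]", {
  u <- c(CAT = 50, CAC = 50,    # 50/50 -> 0
         CAA = 100, CAG = 0,    # 100/0 -> 1
         AAT = 75, AAC = 25)    # 75/25 -> 0.5
  b <- usage_bias(u)
  expect_equal(b$bias[b$aa == "H"], 0)
  expect_equal(b$bias[b$aa == "Q"], 1)
  expect_equal(b$bias[b$aa == "N"], 0.5)
  # single-codon amino acids are skipped even when present
  expect_false("M" %in% usage_bias(c(ATG = 10, CAT = 5, CAC = 5))$aa)
})

test_that("metric tables round-trip through TSV", {
  x <- c(CAT = -0.25, CAC = 0.5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_metric_table(x, path, names_to = "codon", values_to = "csc")
  expect_equal(read_metric_table(path), x)
})
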