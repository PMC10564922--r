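test_that("seed scanning finds complementary windows and nothing else", {
  set.seed(71)
  mi <- "UGAGGUAGUAGGUUGUAUAGUU"
  seed_rc <- rc_rna(substr(mi, 2, 8))
  tgt <- paste0(strrep("C", 49), seed_rc, strrep("C", 30))
  expect_equal(scan_sites(mi, tgt), 50L)

  # no pairing at all
  expect_length(scan_sites(strrep("A", 22), strrep("A", 100)), 0)
  # target shorter than the seed
  expect_length(scan_sites(mi, "ACG"), 0)

  # one G:U wobble in the seed is tolerated by default, two are not
  w1 <- sub("C", "U", seed_rc)          # G:C pair becomes G:U
  tgt1 <- paste0(strrep("C", 20), w1, strrep("C", 20))
  expect_equal(scan_sites(mi, tgt1), 21L)
  w2 <- sub("C", "U", w1)   # second G:C pair also becomes G:U
  expect_false(w2 == w1)
  tgt2 <- paste0(strrep("C", 20), w2, strrep("C", 20))
  expect_length(scan_sites(mi, tgt2), 0)
  expect_equal(scan_sites(mi, tgt2, target_config(max_wobble = 2)), 21L)
})

test_that("duplex energies reproduce an independent stack-sum oracle", {
  set.seed(17)
  for (rep in 1:5) {
    mi <- random_rna(22)
    pad_l <- sample(10:40, 1)
    tgt <- paste0(random_rna(pad_l), rc_rna(mi), random_rna(20))
    j5 <- pad_l + 1           # 5'-most paired target base of the full duplex
    cand <- scan_sites(mi, tgt)
    seed_start <- j5 + 14     # seed complement begins 14 nt into the site
    expect_true(seed_start %in% cand)
    de <- duplex_energy(mi, tgt, seed_start)
    expect_equal(de$total_energy, stack_sum_oracle(mi, tgt, j5),
                 tolerance = 1e-9)
    expect_equal(de$position, j5)
    expect_equal(de$n_paired, 22L)
  }
})

test_that("a single-nucleotide target bulge adds exactly the bulge penalty", {
  set.seed(23)
  mi <- random_rna(22)
  site <- rc_rna(mi)
  # contiguous reference duplex
  tgt0 <- paste0(strrep("C", 20), site, strrep("C", 20))
  e0 <- duplex_energy(mi, tgt0, 21 + 14)$total_energy
  # insert one unpaired target nucleotide between the pairs facing miRNA
  # positions 15 and 16 (inside the 3' extension)
  cut <- 22 - 15            # site bases 1..7 face miRNA 22..16
  tgt1 <- paste0(strrep("C", 20), substr(site, 1, cut), "C",
                 substr(site, cut + 1, 22), strrep("C", 20))
  e1 <- duplex_energy(mi, tgt1, 22 + 14)$total_energy
  expect_equal(e1, e0 + nn_parameters()$bulge1, tolerance = 1e-9)
})

test_that("seed-only pairing stays above the -20 kcal/mol gate", {
  mi <- "UGAGGUAGUAGGUUGUAUAGUU"
  # seed complement embedded in poly-A so no 3' support can pair
  tgt <- paste0(strrep("A", 30), rc_rna(substr(mi, 2, 8)), strrep("A", 30))
  cand <- scan_sites(mi, tgt)
  expect_equal(cand, 31L)
  e <- duplex_energy(mi, tgt, 31L)$total_energy
  expect_gt(e, -20)
  hits <- predict_targets(c(mi = mi), c(t = tgt))
  expect_equal(nrow(hits), 0)
})

test_that("predict_targets recovers planted sites, gates on energy, and is deterministic", {
  b <- simulate_study(small_config(seed = 64))
  mre <- b$ground_truth$mre
  expect_gt(nrow(mre), 5)
  for (r in seq_len(nrow(mre))) {
    cls <- if (mre$target_class[r] == "circRNA") "circrna" else "mrna"
    hits <- predict_targets(b$sequences$mirna[mre$mirna_id[r]],
                            b$sequences[[cls]][mre$target_id[r]])
    expect_true(nrow(hits) >= 1)
    expect_true(mre$position[r] %in% hits$position)
  }

  # energy gate: tightening the threshold below a known hit's energy removes it
  mi <- b$sequences$mirna[mre$mirna_id[1]]
  cls <- if (mre$target_class[1] == "circRNA") "circrna" else "mrna"
  tg <- b$sequences[[cls]][mre$target_id[1]]
  h <- predict_targets(mi, tg)
  expect_true(all(h$total_energy <= -20))
  tighter <- target_config(energy_threshold = min(h$total_energy) - 0.5)
  expect_equal(nrow(predict_targets(mi, tg, tighter)), 0)

  # reversing the target destroys the planted hit
  rev_tg <- setNames(paste(rev(strsplit(tg[[1]], "")[[1]]), collapse = ""),
                     names(tg))
  hrev <- predict_targets(mi, rev_tg)
  expect_false(any(hrev$position == mre$position[1]))

  # determinism and duplicate-ID contract
  mis <- b$sequences$mirna[unique(mre$mirna_id)]
  tgs <- b$sequences$circrna[unique(mre$target_id[mre$target_class == "circRNA"])]
  h1 <- predict_targets(mis, tgs)
  h2 <- predict_targets(mis, tgs)
  expect_identical(h1, h2)
  dup <- c(mis, setNames(mis[1], names(mis)[1]))
  expect_error(predict_targets(dup, tgs), "duplicate")

  # empty target set
  expect_equal(nrow(predict_targets(mis, character(0))), 0)
})
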