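test_that("pedigree construction validates structure strictly", {
  good <- data.frame(id = c("A", "B"), sire = c(NA, NA), dam = c(NA, NA),
                     sex = c("M", "F"), birth_year = 0, location = "captive")
  expect_s3_class(pedigree(good), "wolf_pedigree")

  dup <- good; dup$id <- c("A", "A")
  expect_error(pedigree(dup), "duplicate")

  bad_parent <- good; bad_parent$sire[2] <- "ZZZ"
  expect_error(pedigree(bad_parent), "absent")

  wrong_sex <- data.frame(id = c("A", "B", "C"), sire = c(NA, NA, "A"),
                          dam = c(NA, NA, "B"), sex = c("F", "M", "F"),
                          birth_year = c(0, 0, 1), location = "captive")
  expect_error(pedigree(wrong_sex), "sire must be male|dam must be female")

  self_par <- data.frame(id = "A", sire = "A", dam = NA, sex = "M",
                         birth_year = 0, location = "wild")
  expect_error(pedigree(self_par), "parent ids absent|self-parentage")

  time_loop <- data.frame(id = c("A", "B", "C"), sire = c(NA, NA, "A"),
                          dam = c(NA, NA, "B"), sex = c("M", "F", "F"),
                          birth_year = c(1, 1, 0), location = "captive")
  expect_error(pedigree(time_loop), "strictly less")
})

test_that("pedigree file i/o round-trips and encodes unknown parents as 0", {
  ped <- family_pedigree()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pedigree(ped, path)
  txt <- readLines(path)
  expect_match(txt[1], "^id\tsire\tdam\tsex\tbirth_year\tlocation$")
  expect_true(any(grepl("\t0\t0\t", txt)))
  ped2 <- read_pedigree(path)
  expect_equal(as.data.frame(ped2), as.data.frame(ped))
  expect_setequal(founders(ped2), c("A", "B", "E"))
})

test_that("kinship matches closed forms and is symmetric and bounded", {
  ped <- family_pedigree()
  expect_identical(kinship(ped, "A", "B"), 0)      # distinct founders
  expect_identical(kinship(ped, "C", "D"), 0.25)   # full siblings
  expect_identical(kinship(ped, "A", "C"), 0.25)   # parent-offspring
  K <- kinship_matrix(ped)
  expect_equal(K, t(K))
  expect_true(all(diag(K) >= 0.5))
  expect_true(all(K >= 0 & K <= 1))
  expect_error(kinship(ped, "A", "nope"), "unknown id")
})

test_that("inbreeding coefficient follows parent kinship; unknown sides give F = 0", {
  ped <- family_pedigree()
  expect_identical(inbreeding_coefficient(ped, "A"), 0)   # founder
  sib_child <- rbind(as.data.frame(ped),
                     data.frame(id = "X", sire = "D", dam = "C", sex = "F",
                                birth_year = 2, location = "captive"))
  ped2 <- pedigree(sib_child)
  expect_identical(inbreeding_coefficient(ped2, "X"), 0.25)
  # parent-offspring mating in an otherwise outbred pedigree
  po <- pedigree(data.frame(
    id = c("P", "Q", "R", "S"), sire = c(NA, NA, "P", "P"),
    dam = c(NA, NA, "Q", "R"), sex = c("M", "F", "F", "F"),
    birth_year = c(0, 0, 1, 2), location = "wild"))
  expect_identical(inbreeding_coefficient(po, "S"), 0.25)
  # one known parent: phantom founder convention, F = 0
  half <- pedigree(data.frame(
    id = c("P", "H"), sire = c(NA, "P"), dam = c(NA, NA),
    sex = c("M", "F"), birth_year = c(0, 1), location = "wild"))
  expect_identical(inbreeding_coefficient(half, "H"), 0)
})

test_that("recursive kinship on a looped pedigree agrees with an independent gene-drop estimate", {
  ped <- loop_pedigree()
  # independent oracle: per-replicate gene drop written from scratch
  drop_once <- function(ped) {
    n <- nrow(ped)
    si <- match(ped$sire, ped$id); di <- match(ped$dam, ped$id)
    a1 <- integer(n); a2 <- integer(n); lab <- 0L
    for (i in seq_len(n)) {
      a1[i] <- if (is.na(si[i])) (lab <- lab + 1L) else
        if (runif(1) < 0.5) a1[si[i]] else a2[si[i]]
      a2[i] <- if (is.na(di[i])) (lab <- lab + 1L) else
        if (runif(1) < 0.5) a1[di[i]] else a2[di[i]]
    }
    cbind(a1, a2)
  }
  set.seed(424)
  n_rep <- 1e5
  x <- ped_pair <- match(c("U1", "T2"), ped$id)
  ibd <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    al <- drop_once(ped)
    g1 <- al[ped_pair[1], ]; g2 <- al[ped_pair[2], ]
    ibd[r] <- mean(outer(g1, g2, "=="))
  }
  est <- mean(ibd)
  se <- sd(ibd) / sqrt(n_rep)
  expect_lt(abs(kinship(ped, "U1", "T2") - est), 3 * se)
})
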