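# Shorthand-name parsing, formula construction and accurate-mass matching.

test_that("shorthand names parse into the expected class, chains and flags", {
  st <- parse_lipid_name("ST(d18:1/24:0)")
  expect_equal(st$lipid_class, "ST")
  expect_equal(st$chains[[1]][c("prefix", "carbons", "double_bonds")],
               list(prefix = "d", carbons = 18L, double_bonds = 1L))
  expect_equal(st$chains[[2]]$carbons, 24L)
  expect_false(st$hydroxylated)

  pl <- parse_lipid_name("PE(P-18:0/22:6)")
  expect_equal(pl$lipid_class, "PE-P")
  expect_equal(pl$total_carbons, 40L)
  expect_equal(pl$total_double_bonds, 6L)

  gm <- parse_lipid_name("GM1(d18:1/18:0)")
  expect_equal(gm$lipid_class, "GM1")

  oh <- parse_lipid_name("ST(d18:1/24:0(2OH))")
  expect_true(oh$hydroxylated)

  # total-composition sphingolipid and bare sphingoid prefix
  pc <- parse_lipid_name("PE-Cer(36:1)")
  expect_equal(pc$lipid_class, "PE-Cer")
  expect_equal(pc$total_carbons, 36L)
  hx <- parse_lipid_name("HexCer(18:1/14:0)")
  expect_equal(hx$chains[[1]]$prefix, "d")
  expect_equal(hx$name, "HexCer(d18:1/14:0)")

  # lyso shorthand: single-chain PA/PE/PI and the alternative class spelling
  expect_equal(parse_lipid_name("PE(18:0)")$lipid_class, "LPE")
  expect_equal(parse_lipid_name("PI(20:4)")$lipid_class, "LPI")
  expect_equal(parse_lipid_name("Cer-PE(36:1)")$lipid_class, "PE-Cer")
  expect_equal(parse_lipid_name("PE (18:1/18:0)")$name, "PE(18:1/18:0)")
})

test_that("unparseable names fail with informative errors", {
  expect_error(parse_lipid_name("ST(d18:1/24:q)"), "chain token")
  expect_error(parse_lipid_name("XX(18:0/18:0)"), "unsupported lipid class")
  expect_error(parse_lipid_name("ST18:1"), "expected CLASS")
  expect_error(parse_lipid_name("PA(1:0)"), "fewer than 2 carbons")
  expect_error(parse_lipid_name("PA(18:12/18:0)"), "double-bond")
})

test_that("construction rules reproduce hand-computed formulas", {
  fmt <- function(name) format(parse_lipid_name(name)$formula)
  expect_equal(fmt("Cer(d18:1/18:0)"), "C36H71NO3")
  expect_equal(fmt("GM3(d18:1/18:0)"), "C59H108N2O21")
  expect_equal(fmt("PA(16:0/16:0)"), "C35H69O8P")
  expect_equal(fmt("ST(d18:1/24:0)"), "C48H93NO11S")
  expect_equal(fmt("CPA(18:0)"), "C21H41O6P")
})

test_that("monoisotopic masses match frozen reference values", {
  m <- function(name) round(parse_lipid_name(name)$neutral_mass, 4)
  expect_equal(m("Cer(d18:1/18:0)"), 565.5434)
  expect_equal(m("CerP(d18:1/18:0)"), 645.5097)
  expect_equal(m("ST(d18:1/24:0)"), 891.6469)
  expect_equal(m("GM1(d18:1/18:0)"), 1545.8767)
  expect_equal(m("PE(P-18:0/22:6)"), 775.5516)
  expect_equal(m("LPA(18:0)"), 438.2746)   # genuine lyso-PA, not the cyclic form
  expect_equal(m("CPA(18:0)"), 420.2641)
  expect_equal(monoisotopic_mass(element_counts()), 0)
  expect_error(monoisotopic_mass(c(Xx = 3)), "unknown element")
})

test_that("[M-H]- adduct subtracts the electron-corrected proton mass", {
  expect_equal(round(adduct_mz(891.6469), 4), 890.6396)
  expect_equal(round(adduct_mz(645.5097), 4), 644.5024)
  expect_error(adduct_mz(0.5), "non-positive")
  expect_error(adduct_mz(700, "[M+H]+"), "unsupported adduct")
})

test_that("every clean panel species reproduces its reference mass to 5e-4 Da", {
  panel <- brain_lipid_panel()
  clean <- panel[panel$flag == "", , drop = FALSE]
  expect_gte(nrow(clean), 36)
  computed <- vapply(clean$name, function(n) parse_lipid_name(n)$neutral_mass,
                     numeric(1))
  expect_lt(max(abs(computed - clean$reference_mass)), 5e-4)
  # aliases parse to the same species, except the cyclic-PA row whose listed
  # spelling LPA(18:0) names the open (hydrated) form: CPA = LPA - H2O
  has_alias <- clean[clean$alias != "" & clean$lipid_class != "CPA", , drop = FALSE]
  for (i in seq_len(nrow(has_alias))) {
    expect_equal(parse_lipid_name(has_alias$alias[i])$neutral_mass,
                 parse_lipid_name(has_alias$name[i])$neutral_mass)
  }
  cpa <- clean[clean$lipid_class == "CPA", ]
  expect_equal(parse_lipid_name(cpa$alias)$neutral_mass,
               parse_lipid_name(cpa$name)$neutral_mass +
                 monoisotopic_mass(element_counts(H = 2, O = 1)))
})

test_that("high-resolution observed values lie within 2 ppm of computed [M-H]-", {
  panel <- brain_lipid_panel()   # excluded row dropped; typo row kept
  obs <- panel[!is.na(panel$orbitrap_mz), , drop = FALSE]
  expect_gte(nrow(obs), 30)
  theo <- vapply(obs$name, function(n) adduct_mz(parse_lipid_name(n)$neutral_mass),
                 numeric(1))
  ppm <- 1e6 * (obs$orbitrap_mz - theo) / theo
  expect_true(all(abs(ppm) <= 2))
})

test_that("flagged panel rows behave as documented", {
  full <- brain_lipid_panel(include_excluded = TRUE)
  # reference mass of the typo row disagrees with its own observed value,
  # while the parser-computed mass agrees with it
  typo <- full[full$flag == "theor_typo", ]
  expect_equal(typo$name, "LPI(20:4)")
  sp <- parse_lipid_name(typo$name)
  expect_gt(abs(sp$neutral_mass - typo$reference_mass), 0.1)
  expect_lt(abs(adduct_mz(sp$neutral_mass) - typo$orbitrap_mz) /
              typo$orbitrap_mz * 1e6, 2)
  # the excluded row's reference mass corresponds to a different double-bond
  # count than its name claims
  excl <- full[full$flag == "excluded", ]
  expect_equal(excl$name, "PA(16:0/18:1)")
  expect_gt(abs(parse_lipid_name(excl$name)$neutral_mass - excl$reference_mass), 1)
})

test_that("peak matching finds the documented best hits at 2 ppm", {
  lib <- build_mass_library(brain_lipid_panel())
  b <- best_hits(c(890.6398, 619.2890, 500.0000), lib, tol_ppm = 2)
  expect_equal(b$name[1], "ST(d18:1/24:0)")
  expect_lt(abs(b$ppm_error[1]), 2)
  expect_equal(b$name[2], "LPI(20:4)")
  expect_true(is.na(b$name[3]))
  expect_error(match_peaks(890, structure(list(), class = "mass_library")),
               "non-empty")
})

test_that("matching agrees with a brute-force ppm oracle and is monotone in tolerance", {
  lib <- build_mass_library(brain_lipid_panel())
  set.seed(42)
  # queries: jittered library masses plus uniform decoys
  queries <- c(lib$mz * (1 + runif(nrow(lib), -3e-6, 3e-6)),
               runif(30, 400, 1600))
  for (tol in c(0.5, 2, 5)) {
    got <- match_peaks(queries, lib, tol_ppm = tol)
    brute <- do.call(rbind, lapply(queries, function(o) {
      ppm <- 1e6 * (o - lib$mz) / lib$mz
      k <- which(abs(ppm) <= tol)
      if (!length(k)) return(NULL)
      ord <- order(abs(ppm[k]), lib$name[k])
      data.frame(observed_mz = o, name = lib$name[k][ord],
                 adduct = lib$adduct[k][ord], theoretical_mz = lib$mz[k][ord],
                 ppm_error = ppm[k][ord], stringsAsFactors = FALSE)
    }))
    rownames(brute) <- NULL
    expect_equal(got, brute)
  }
  # monotonicity: hits at a smaller tolerance are a subset of hits at a larger
  small <- match_peaks(queries, lib, tol_ppm = 1)
  large <- match_peaks(queries, lib, tol_ppm = 3)
  key <- function(h) paste(h$observed_mz, h$name, h$adduct)
  expect_true(all(key(small) %in% key(large)))
})

test_that("library construction orders entries and rejects duplicates", {
  lib <- build_mass_library(c("ST(d18:1/24:0)", "GM1(d18:1/18:0)",
                              "ST(d18:1/24:0)"))
  expect_equal(nrow(lib), 2L)
  expect_true(!is.unsorted(lib$mz))
})

test_that("annotation report CSV round-trips", {
  lib <- build_mass_library(brain_lipid_panel())
  hits <- match_peaks(c(890.6398, 644.5025), lib)
  path <- withr::local_tempfile(fileext = ".csv")
  write_annotation_csv(hits, path)
  back <- read_annotation_csv(path)
  expect_equal(back$species, hits$name)
  expect_equal(back$observed_mz, hits$observed_mz)
})
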