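test_that("classify_growth reproduces the worked cohort rows", {
  # cholangiocarcinoma-style row
  expect_equal(classify_growth(TRUE, "fluid", "solid", TRUE, "sharp")$type,
               4L)
  # hepatocellular-adenoma-style row
  expect_equal(classify_growth(FALSE, "solid", "solid", TRUE,
                               "sharp")$type, 1L)
  # necrosis-style row (control regime and heterogeneity redundant)
  expect_equal(classify_growth(FALSE, "fluid", NA, NA, "diffuse")$type,
               3L)
})

test_that("growth pattern identity and validity hold", {
  gp <- growth_pattern(TRUE, FALSE)
  expect_equal(gp$type, 2L)
  gp <- growth_pattern(TRUE, TRUE)
  expect_equal(gp$type, 4L)
})

test_that("enumeration yields 72 internally consistent rows", {
  ec <- enumerate_combinations()
  expect_equal(nrow(ec), 72L)
  expect_equal(ec$type,
               1L + as.integer(ec$displacing) +
                 2L * as.integer(ec$infiltrative))
  # softer tumours with sharp fronts are always type 1
  expect_true(all(ec$type[!ec$stiffer & ec$front == "sharp"] == 1L))
  # diffuse fronts always enable infiltration: types 3 or 4 only
  expect_true(all(ec$type[ec$front == "diffuse"] %in% c(3L, 4L)))
})

test_that("type is monotone in front texture and stiffness ratio", {
  ec <- enumerate_combinations()
  key <- function(d) paste(d$stiffer, d$tumor_regime, d$control_regime,
                           d$heterogeneous)
  sharp <- ec[ec$front == "sharp", ]
  diffuse <- ec[ec$front == "diffuse", ]
  diffuse <- diffuse[match(key(sharp), key(diffuse)), ]
  expect_true(all(diffuse$type >= sharp$type))
  key2 <- function(d) paste(d$tumor_regime, d$control_regime,
                            d$heterogeneous, d$front)
  soft <- ec[!ec$stiffer, ]
  stiff <- ec[ec$stiffer, ]
  stiff <- stiff[match(key2(soft), key2(stiff)), ]
  expect_true(all(stiff$type >= soft$type))
})

test_that("redundant inputs resolve, fall back, or report ambiguity", {
  # front redundant but the tumour is fluid: outcome does not depend
  # on it
  expect_equal(classify_growth(TRUE, "fluid", "transitional", TRUE,
                               "redundant")$type, 4L)
  # front pivots the type: dual answer by default
  amb <- classify_growth(TRUE, "solid", "solid", FALSE, "redundant")
  expect_true(is.na(amb$type))
  expect_equal(amb$possible_types, c(1L, 3L))
  expect_error(classify_growth(TRUE, "solid", "solid", FALSE, "redundant",
                               on_ambiguity = "error"), "ambiguous")
  # Saffman-Taylor fallback decides when moduli are available
  phi_t <- phase_from_fluidity(-0.54)
  phi_c <- phase_from_fluidity(-0.17)
  mod <- list(phi_tumor = phi_t, phi_control = phi_c,
              g_tumor = modulus_from_speed(1.07, phi_t),
              g_control = modulus_from_speed(1.42, phi_c))
  res <- classify_growth(TRUE, "solid", "solid", FALSE, "redundant",
                         moduli = mod)
  expect_equal(res$type, 3L) # unstable boundary -> diffuse front
})

test_that("transitional stiffer tumours carry the type 2/4 annotation", {
  gp <- classify_growth(TRUE, "transitional", "solid", TRUE, "sharp")
  expect_equal(gp$type, 2L)
  expect_match(gp$annotation, "2/4")
})

test_that("stiffer_than_control follows Welch's test on the summaries", {
  # adenoma vs adjacent tissue: tiny difference, not significant
  expect_false(stiffer_than_control(list(mean = 1.41, sd = 0.21, n = 15),
                                    list(mean = 1.38, sd = 0.12, n = 15)))
  # cholangiocarcinoma: clearly stiffer
  res <- stiffer_than_control(list(mean = 2.57, sd = 0.90, n = 12),
                              list(mean = 1.72, sd = 0.29, n = 12))
  expect_true(res)
  # independent recomputation of the Welch statistic
  se <- sqrt(0.90^2 / 12 + 0.29^2 / 12)
  expect_equal(attr(res, "t"), (2.57 - 1.72) / se, tolerance = 1e-12)
  expect_false(stiffer_than_control(list(mean = 2, sd = 0.3, n = 10),
                                    list(mean = 2, sd = 0.3, n = 10)))
  expect_warning(
    one <- stiffer_than_control(list(mean = 2, sd = 0, n = 1),
                                list(mean = 1, sd = 0, n = 1)),
    "n < 2")
  expect_true(one)
})

test_that("packaged fixture has the published structure", {
  fx <- tumor_meta_fixture()
  expect_equal(nrow(fx), 27L)
  hcc <- fx[fx$entity == "Liver - HCC" & fx$role == "tumor", ]
  expect_equal(hcc$c_mean, 2.54)
  expect_equal(hcc$c_sd, 0.64)
  expect_equal(hcc$fluidity_mean, 0.53)
  expect_equal(hcc$fluidity_sd, 0.37)
  expect_equal(hcc$n, 22L)
  # colorectal has two control groups (adjacent tissue + volunteers)
  crc <- fx[fx$entity == "Colorectal Ca" & fx$role == "control", ]
  expect_setequal(crc$control_tag, c("DTT", "HV"))
})

test_that("delta table reproduces the arrow arithmetic", {
  dt <- delta_table()
  hem <- dt[dt$entity == "Liver - HEM", ]
  expect_equal(hem$delta_c, 0.60, tolerance = 1e-12)
  expect_equal(hem$delta_fluidity, 0.45, tolerance = 1e-12)
  hca <- dt[dt$entity == "Liver - HCA", ]
  expect_equal(hca$delta_c, 0.03, tolerance = 1e-12)
  # one arrow per control group: prostate zones and colorectal duals
  expect_equal(sum(dt$entity == "Prostate PCa 1"), 2L)
  expect_equal(sum(dt$entity == "Colorectal Ca"), 2L)
  expect_equal(nrow(dt), 15L)
})

test_that("retrospective classification reproduces the published table", {
  tab <- reproduce_growth_patterns()
  expect_equal(nrow(tab), 11L)
  # every row without a bracketed correction must match exactly
  unbracketed <- is.na(tab$clinical_correction)
  expect_equal(sum(unbracketed), 8L)
  expect_true(all(tab$concordant[unbracketed]))
  # bracketed rows keep the tree output and report the correction
  hem <- tab[tab$entity == "Liver - HEM", ]
  expect_equal(hem$type, 4L)
  expect_equal(hem$clinical_correction, 2L)
  men <- tab[tab$entity == "Brain - MEN", ]
  expect_equal(men$type, 1L)
  expect_equal(men$clinical_correction, 2L)
  # regimes recomputed from the fixture means agree with the printed
  # single-label regimes
  sub <- tab[!is.na(tab$recomputed_tumor_regime), ]
  expect_true(all(sub$recomputed_tumor_regime == sub$tumor_regime))
})
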