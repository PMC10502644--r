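# Growth-pattern classification scheme.
#
# Two independent growth modes are read off multiparametric
# elastography: displacing growth (the tumour pushes its host aside,
# requiring higher stiffness than the host plus mechanical activity)
# and infiltrative cell spreading (cells escape across the boundary,
# signalled by a fluid tumour regime or a diffuse front). Their
# presence/absence combinations define growth-pattern types 1-4 via
# type = 1 + displacing + 2 * infiltrative.

.regime_levels <- c("solid", "transitional", "fluid")

.growth_core <- function(stiffer, tumor_regime, heterogeneous,
                         front_diffuse) {
  if (!stiffer) {
    displacing <- FALSE
    infiltrative <- front_diffuse
  } else {
    # a heterogeneous fluidity distribution is automatically associated
    # with at least partial fluid-like properties, hence activity
    displacing <- tumor_regime %in% c("fluid", "transitional") ||
      isTRUE(heterogeneous)
    infiltrative <- front_diffuse || tumor_regime == "fluid"
  }
  list(displacing = displacing, infiltrative = infiltrative,
       type = 1L + as.integer(displacing) + 2L * as.integer(infiltrative))
}

#' Growth pattern object
#'
#' @param displacing logical: displacing growth present.
#' @param infiltrative logical: infiltrative cell spreading present.
#' @param annotation optional character note.
#' @return object of class `growth_pattern` with `type`
#'   (`1 + displacing + 2 * infiltrative`), `displacing`,
#'   `infiltrative`, `annotation`.
#' @export
growth_pattern <- function(displacing, infiltrative, annotation = NULL) {
  structure(list(type = 1L + as.integer(displacing) +
                   2L * as.integer(infiltrative),
                 displacing = displacing, infiltrative = infiltrative,
                 annotation = annotation),
            class = "growth_pattern")
}

#' @export
print.growth_pattern <- function(x, ...) {
  cat(sprintf("growth pattern type %d (displacing: %s, infiltrative: %s)\n",
              x$type, x$displacing, x$infiltrative))
  if (!is.null(x$annotation)) cat(" note:", x$annotation, "\n")
  invisible(x)
}

#' Classify a tumour's growth pattern from five elastography inputs
#'
#' Decision scheme over (i) whether the tumour is stiffer than its
#' control tissue, (ii) the tumour fluidity regime, (iii) the control
#' fluidity regime, (iv) spatial heterogeneity of the tumour fluidity,
#' and (v) the tumour-front texture:
#' * tumour not stiffer: no displacing growth; infiltrative spreading
#'   iff the front is diffuse (types 1 or 3, front texture alone
#'   decides);
#' * tumour stiffer: displacing growth iff the tumour shows mechanical
#'   activity (fluid or transitional regime, or heterogeneous fluidity
#'   -- heterogeneity implies at least partial fluid-like behaviour);
#'   infiltrative spreading iff the front is diffuse or the tumour
#'   regime is fluid.
#'
#' The control regime is carried because it is one of the five stated
#' inputs (and is used for reporting and the Saffman-Taylor fallback)
#' but does not pivot the reconstructed tree. Inputs marked redundant
#' (`front = "redundant"`, `heterogeneous = NA`) are resolved by
#' evaluating all completions: if every completion yields the same
#' type it is returned; if the front is redundant but moduli are
#' supplied, the Saffman-Taylor criterion decides (unstable boundary
#' = diffuse); otherwise a dual-type answer (or an error, see
#' `on_ambiguity`) results.
#'
#' @param stiffer logical: tumour stiffer than control.
#' @param tumor_regime,control_regime `"solid"`, `"transitional"` or
#'   `"fluid"`; the control regime may be `NA`/redundant or a dual
#'   label such as `"solid/transitional"`.
#' @param heterogeneous logical flag, `NA` when redundant/unknown.
#' @param front `"sharp"`, `"diffuse"` or `"redundant"`.
#' @param moduli optional list `(phi_tumor, phi_control, g_tumor,
#'   g_control)` enabling the Saffman-Taylor fallback when the front
#'   is redundant.
#' @param on_ambiguity `"dual"` returns a `growth_pattern` with a
#'   `possible_types` vector and `type = NA`; `"error"` raises an
#'   ambiguity error listing the possible types.
#' @return a [growth_pattern()] object.
#' @export
classify_growth <- function(stiffer, tumor_regime,
                            control_regime = NA_character_,
                            heterogeneous = NA,
                            front = c("sharp", "diffuse", "redundant"),
                            moduli = NULL,
                            on_ambiguity = c("dual", "error")) {
  front <- match.arg(front)
  on_ambiguity <- match.arg(on_ambiguity)
  tumor_regime <- as.character(tumor_regime)
  stopifnot(isTRUE(stiffer) || isFALSE(stiffer),
            tumor_regime %in% .regime_levels)

  het_opts <- if (is.na(heterogeneous)) c(FALSE, TRUE) else heterogeneous
  front_opts <- if (front == "redundant") c(FALSE, TRUE) else
    front == "diffuse"
  combos <- expand.grid(het = het_opts, fd = front_opts)
  results <- lapply(seq_len(nrow(combos)), function(i) {
    .growth_core(stiffer, tumor_regime, combos$het[i], combos$fd[i])
  })
  types <- vapply(results, `[[`, integer(1), "type")

  if (length(unique(types)) > 1 && front == "redundant" &&
      !is.null(moduli)) {
    unstable <- saffman_taylor_unstable(moduli$phi_tumor,
                                        moduli$phi_control,
                                        moduli$g_tumor, moduli$g_control)
    return(classify_growth(stiffer, tumor_regime, control_regime,
                           heterogeneous,
                           front = if (unstable) "diffuse" else "sharp",
                           on_ambiguity = on_ambiguity))
  }
  if (length(unique(types)) > 1) {
    if (on_ambiguity == "error") {
      stop(sprintf("ambiguous growth pattern: possible types %s",
                   paste(sort(unique(types)), collapse = ", ")),
           call. = FALSE)
    }
    out <- growth_pattern(FALSE, FALSE,
                          annotation = "ambiguous: redundant input pivots the type")
    out$type <- NA_integer_
    out$displacing <- NA
    out$infiltrative <- NA
    out$possible_types <- sort(unique(types))
    return(out)
  }

  res <- results[[1]]
  note <- NULL
  if (stiffer && tumor_regime == "transitional" && !isTRUE(front_opts[1])) {
    note <- paste("transitional tumour fluidity: traits of both solid and",
                  "fluid behaviour possible (type 2/4)")
  }
  growth_pattern(res$displacing, res$infiltrative, annotation = note)
}

#' Enumerate all input combinations of the classification scheme
#'
#' The Cartesian product of the five categorical inputs -- stiffness
#' ratio (2) x tumour regime (3) x control regime (3) x heterogeneity
#' (2) x front texture (2) -- yields 72 rows, each classified by the
#' decision tree.
#'
#' @param thresholds regime thresholds, carried for interface parity
#'   (the enumeration is over labels, so they do not alter the table).
#' @return data.frame with 72 rows and columns `stiffer`,
#'   `tumor_regime`, `control_regime`, `heterogeneous`, `front`,
#'   `displacing`, `infiltrative`, `type`.
#' @export
enumerate_combinations <- function(thresholds = c(-0.1, 0.1)) {
  grid <- expand.grid(stiffer = c(FALSE, TRUE),
                      tumor_regime = .regime_levels,
                      control_regime = .regime_levels,
                      heterogeneous = c(FALSE, TRUE),
                      front = c("sharp", "diffuse"),
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    .growth_core(grid$stiffer[i], grid$tumor_regime[i],
                 grid$heterogeneous[i], grid$front[i] == "diffuse")
  })
  grid$displacing <- vapply(res, `[[`, logical(1), "displacing")
  grid$infiltrative <- vapply(res, `[[`, logical(1), "infiltrative")
  grid$type <- vapply(res, `[[`, integer(1), "type")
  grid
}

#' Welch's t-test from summary statistics
#'
#' @param m1,s1,n1 mean, sd, size of group 1.
#' @param m2,s2,n2 mean, sd, size of group 2.
#' @return list with `t`, `df`, `p` (two-sided).
#' @export
welch_from_summary <- function(m1, s1, n1, m2, s2, n2) {
  v1 <- s1^2 / n1
  v2 <- s2^2 / n2
  t <- (m1 - m2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * stats::pt(abs(t), df, lower.tail = FALSE))
}

#' Is the tumour stiffer than its control tissue?
#'
#' Operationalises the stiffness-ratio input of the classification
#' scheme from group summary statistics: `TRUE` iff the tumour mean
#' exceeds the control mean and Welch's t-test (computed from the
#' summaries) rejects equality at `alpha`.
#'
#' @param tumor,control lists or named vectors with elements `mean`,
#'   `sd`, `n`.
#' @param alpha significance level.
#' @return logical flag with attributes `t`, `df`, `p`.
#' @export
stiffer_than_control <- function(tumor, control, alpha = 0.05) {
  tm <- as.list(tumor)
  cm <- as.list(control)
  if (tm$n < 2 || cm$n < 2) {
    warning("cannot test with n < 2; falling back to mean comparison",
            call. = FALSE)
    return(structure(tm$mean > cm$mean, t = NA_real_, df = NA_real_,
                     p = NA_real_))
  }
  w <- welch_from_summary(tm$mean, tm$sd, tm$n, cm$mean, cm$sd, cm$n)
  structure(tm$mean > cm$mean && w$p < alpha,
            t = w$t, df = w$df, p = w$p)
}

#' Packaged meta-analysis fixture of tumour mechanics
#'
#' Per-entity stiffness (shear-wave speed, m/s) and fluidity summary
#' statistics (mean, sd, N) for tumour and control tissue, collected
#' from published in vivo multifrequency MRE studies across liver,
#' brain, pancreas, prostate and colorectum. Control-tissue origins:
#' DTT (distal tumour-adjacent tissue), HV (healthy volunteers), CLH
#' (contralateral hemisphere white matter), BPH (benign prostatic
#' hyperplasia); prostate controls are split by anatomical zone
#' (PZ/TZ). Brain speeds were converted from \eqn{|G^*|} via the
#' speed--modulus relation.
#'
#' @return data.frame with one row per tumour or control group.
#' @export
tumor_meta_fixture <- function() {
  path <- system.file("extdata", "tumor_meta_fixture.csv",
                      package = "fluidmre", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(zone = "character",
                                 control_tag = "character"))
}

#' Packaged growth-classification input annotations
#'
#' The five categorical classifier inputs per entity, as used in the
#' retrospective application of the scheme: stiffness ratio, tumour
#' and control fluidity regimes, heterogeneity and front texture (the
#' latter two assigned putatively from histopathology since bulk MRE
#' does not resolve them), plus the published growth pattern (with
#' clinical-context corrections in brackets) and clinical diagnosis.
#'
#' @return data.frame with one row per entity.
#' @export
growth_annotations <- function() {
  path <- system.file("extdata", "growth_annotations.csv",
                      package = "fluidmre", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

.parse_regime <- function(label) {
  x <- tolower(trimws(label))
  x <- sub("\\.$", "", x)
  map <- c(solid = "solid", trans = "transitional", fluid = "fluid",
           red = NA_character_)
  key <- sub("\\..*$", "", sub("/.*$", "", x)) # first label of a dual
  key <- sub("\\.$", "", key)
  unname(map[match(key, names(map))])
}

#' Retrospective growth-pattern classification of the packaged cohort
#'
#' Runs [classify_growth()] on the packaged per-entity annotations and
#' compares the computed type with the published one. Bracketed
#' clinical-context corrections in the published table (knowledge
#' external to the scheme, e.g. T2-hyperintense haemangiomas) are
#' reported in `clinical_correction`, never as tree output. Where the
#' entity maps onto the meta-analysis fixture, the tumour/control
#' regimes recomputed from the fixture means are attached for
#' cross-checking.
#'
#' @param annotations data.frame as from [growth_annotations()].
#' @param fixture data.frame as from [tumor_meta_fixture()].
#' @param thresholds regime thresholds for the recomputed labels.
#' @return data.frame with one row per entity: the parsed inputs, the
#'   computed `type`, the published `printed_type`,
#'   `clinical_correction`, `concordant`, and recomputed regimes.
#' @export
reproduce_growth_patterns <- function(annotations = growth_annotations(),
                                      fixture = tumor_meta_fixture(),
                                      thresholds = c(-0.1, 0.1)) {
  n <- nrow(annotations)
  out <- data.frame(entity = annotations$entity,
                    stiffer = annotations$stiffness_ratio == ">1",
                    tumor_regime = .parse_regime(annotations$fluidity_tumor),
                    control_regime =
                      .parse_regime(annotations$fluidity_control),
                    heterogeneous = grepl("\\+", annotations$heterogeneity),
                    front = tolower(sub("\\.$", "",
                                        annotations$front)),
                    stringsAsFactors = FALSE)
  out$front[out$front == "red"] <- "redundant"
  out$type <- NA_integer_
  for (i in seq_len(n)) {
    gp <- classify_growth(out$stiffer[i], out$tumor_regime[i],
                          out$control_regime[i], out$heterogeneous[i],
                          out$front[i])
    out$type[i] <- gp$type
  }
  printed <- annotations$printed_pattern
  out$printed_type <- as.integer(sub("^([0-9]+).*$", "\\1", printed))
  corr <- regmatches(printed, regexpr("\\(([0-9]+)\\)", printed))
  out$clinical_correction <- NA_integer_
  has <- grepl("\\(", printed)
  out$clinical_correction[has] <- as.integer(gsub("[()]", "", corr))
  out$concordant <- out$type == out$printed_type

  # recomputed regimes from the fixture means, where a mapping exists
  out$recomputed_tumor_regime <- NA_character_
  out$recomputed_control_regime <- NA_character_
  for (i in seq_len(n)) {
    key <- annotations$meta_entity[i]
    if (is.na(key) || !nzchar(key)) next
    tum <- fixture[fixture$entity == key & fixture$role == "tumor", ]
    ctl <- fixture[fixture$entity == key & fixture$role == "control", ]
    if (nrow(tum) == 1) {
      out$recomputed_tumor_regime[i] <-
        as.character(regime_classify(tum$fluidity_mean, thresholds))
    }
    if (nrow(ctl) >= 1) {
      out$recomputed_control_regime[i] <-
        paste(unique(as.character(regime_classify(ctl$fluidity_mean,
                                                  thresholds))),
              collapse = "/")
    }
  }
  out
}

#' Stiffness / fluidity deltas of tumour versus control
#'
#' Arrow arithmetic over the meta-analysis fixture: for every entity
#' and every control group (multi-control entities get one arrow per
#' control), the change in shear-wave speed and fluidity from control
#' to tumour.
#'
#' @param fixture data.frame as from [tumor_meta_fixture()].
#' @return data.frame with columns `entity`, `control_tag`, `zone`,
#'   `delta_c`, `delta_fluidity`.
#' @export
delta_table <- function(fixture = tumor_meta_fixture()) {
  tum <- fixture[fixture$role == "tumor", ]
  ctl <- fixture[fixture$role == "control", ]
  rows <- lapply(seq_len(nrow(ctl)), function(i) {
    t1 <- tum[tum$entity == ctl$entity[i], ]
    if (nrow(t1) != 1) return(NULL)
    data.frame(entity = ctl$entity[i], control_tag = ctl$control_tag[i],
               zone = ctl$zone[i],
               delta_c = t1$c_mean - ctl$c_mean[i],
               delta_fluidity = t1$fluidity_mean - ctl$fluidity_mean[i],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
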