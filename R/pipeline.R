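## Four-stage workflow orchestration: primary screen -> confirmation ->
## dose-effect synergy quantification -> HCA validation, on synthetic plates
## with known ground truth (or on user-supplied CSVs stage by stage).

#' Standard screen-plate layouts
#'
#' \code{primaryScreenLayout}: 16 x 24 plate with the first two columns as
#' negative controls, the last two as positive controls, and library
#' compounds (one well each, up to 320) filling columns 3-22 row-major.
#' \code{confirmationLayout}: edge-free redesign for re-testing -- the first
#' and last rows and columns are empty, negative controls in columns 3-4,
#' positive controls in columns 21-22, compounds in columns 5-20 of rows
#' 2-15 (up to 224).
#'
#' @param plateId plate identifier.
#' @param compounds character vector of library compound ids.
#' @param concentration library compound concentration (uM), default 10.
#' @param ptDrug,ptConcentration Pt-drug annotation for a combination plate
#'   (added to every non-empty well, controls included), or NULL.
#' @return a \linkS4class{PlateLayout}.
#' @export
primaryScreenLayout <- function(plateId, compounds, concentration = 10,
                                ptDrug = NULL, ptConcentration = NULL) {
  if (length(compounds) > 16 * 20)
    stop("at most 320 library compounds fit on a primary screen plate")
  grid <- expand.grid(col = 1:24, row = 1:16)[, c("row", "col")]
  role <- rep("empty", nrow(grid))
  role[grid$col %in% 1:2] <- "negative_control"
  role[grid$col %in% 23:24] <- "positive_control"
  lib <- which(grid$col %in% 3:22)
  lib <- lib[order(grid$row[lib], grid$col[lib])][seq_along(compounds)]
  role[lib] <- if (is.null(ptDrug)) "library" else "combination"
  w <- data.frame(grid, role = role, compound_id = NA_character_,
                  concentration = NA_real_, pt_drug_id = NA_character_,
                  pt_concentration = NA_real_)
  w$compound_id[lib] <- compounds
  w$concentration[lib] <- concentration
  if (!is.null(ptDrug)) {
    ne <- w$role != "empty"
    w$pt_drug_id[ne] <- ptDrug
    w$pt_concentration[ne] <- ptConcentration
  }
  PlateLayout(plateId, w[w$role != "empty", , drop = FALSE])
}

#' @rdname primaryScreenLayout
#' @export
confirmationLayout <- function(plateId, compounds, concentration = 10,
                               ptDrug = NULL, ptConcentration = NULL) {
  if (length(compounds) > 14 * 16)
    stop("at most 224 compounds fit on a confirmation plate")
  grid <- expand.grid(col = 3:22, row = 2:15)[, c("row", "col")]
  role <- rep(NA_character_, nrow(grid))
  role[grid$col %in% 3:4] <- "negative_control"
  role[grid$col %in% 21:22] <- "positive_control"
  lib <- which(grid$col %in% 5:20)
  lib <- lib[order(grid$row[lib], grid$col[lib])][seq_along(compounds)]
  role[is.na(role)] <- "empty"
  role[lib] <- if (is.null(ptDrug)) "library" else "combination"
  w <- data.frame(grid, role = role, compound_id = NA_character_,
                  concentration = NA_real_, pt_drug_id = NA_character_,
                  pt_concentration = NA_real_)
  w$compound_id[lib] <- compounds
  w$concentration[lib] <- concentration
  if (!is.null(ptDrug)) {
    ne <- w$role != "empty"
    w$pt_drug_id[ne] <- ptDrug
    w$pt_concentration[ne] <- ptConcentration
  }
  PlateLayout(plateId, w[w$role != "empty", , drop = FALSE])
}

#' Pipeline configuration
#'
#' Assembles (or reads from a YAML key-value file) the configuration of the
#' synthetic end-to-end run.  Defaults mirror the reference assay: a Pt drug
#' at its IC50 against a 100-compound library at 10 uM, duplicate plates,
#' noise cv 0.05, hit rule "as_printed", r > 0.85, Z' > 0.4, effect levels
#' 0.5/0.75/0.9/0.95.
#'
#' @param seed integer master seed; every stage seed derives from it.
#' @param out_dir output directory for stage CSVs and the manifest.
#' @param stages subset of c("screen", "confirm", "synergy", "hca").
#' @param n_compounds library size of the synthetic screen.
#' @param planted named numeric vector: ground-truth CI at fa = 0.5 for
#'   planted interacting compounds (e.g. c(cmpd001 = 0.3)); all other
#'   compounds are Loewe-additive with the Pt drug.
#' @param pt_drug,pt_dm,pt_m,pt_concentration Pt drug identity and
#'   ground-truth curve (defaults: cisplatin, Dm 15 uM, m 1.5, tested at its
#'   IC50 of 15 uM).
#' @param cv noise coefficient of variation.
#' @param ctrl_signal expected negative-control fluorescence.
#' @param rule_variant hit rule variant, see \code{\link{callHits}}.
#' @param r_threshold,z_threshold fit and QC gates.
#' @param effect_levels CI reporting levels.
#' @param n_rep dose-response replicates per concentration.
#' @param max_synergy at most this many confirmed hits advance to stage 3.
#' @return a list of class "PipelineConfig".
#' @export
pipelineConfig <- function(seed = 1L, out_dir = tempfile("run"),
                           stages = c("screen", "confirm", "synergy", "hca"),
                           n_compounds = 100L,
                           planted = c(cmpd001 = 0.3),
                           pt_drug = "cisplatin", pt_dm = 15, pt_m = 1.5,
                           pt_concentration = 15, cv = 0.05,
                           ctrl_signal = 1e4,
                           rule_variant = "as_printed", r_threshold = 0.85,
                           z_threshold = 0.4,
                           effect_levels = c(0.5, 0.75, 0.9, 0.95),
                           n_rep = 4L, max_synergy = 10L) {
  cfg <- list(seed = as.integer(seed), out_dir = out_dir, stages = stages,
              n_compounds = as.integer(n_compounds), planted = planted,
              pt_drug = pt_drug, pt_dm = pt_dm, pt_m = pt_m,
              pt_concentration = pt_concentration, cv = cv,
              ctrl_signal = ctrl_signal, rule_variant = rule_variant,
              r_threshold = r_threshold, z_threshold = z_threshold,
              effect_levels = effect_levels, n_rep = as.integer(n_rep),
              max_synergy = as.integer(max_synergy))
  stopifnot(all(cfg$stages %in% c("screen", "confirm", "synergy", "hca")),
            cfg$r_threshold > 0, cfg$r_threshold < 1, cfg$cv >= 0)
  structure(cfg, class = "PipelineConfig")
}

#' @rdname pipelineConfig
#' @param path YAML file with any subset of the fields above.
#' @export
readPipelineConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$planted)) vals$planted <- unlist(vals$planted)
  do.call(pipelineConfig, vals)
}

## Deterministic ground truth of the synthetic library: per-compound
## median-effect parameters and the screen-level score boost of planted pairs.
.screen_truth <- function(cfg) {
  ids <- sprintf("cmpd%03d", seq_len(cfg$n_compounds))
  .with_seed(cfg$seed, {
    dm <- rlnorm(cfg$n_compounds, log(30), 0.4)
    m <- runif(cfg$n_compounds, 1, 2.5)
    alone <- .me_fa(10, dm, m)   # library tested at 10 uM
    combo <- alone               # additive: equal score vs the Pt baseline
    planted_idx <- match(names(cfg$planted), ids)
    if (anyNA(planted_idx))
      stop("planted compound(s) not in the library: ",
           paste(names(cfg$planted)[is.na(planted_idx)], collapse = ", "))
    combo[planted_idx] <- pmin(alone[planted_idx] + 0.35, 0.95)
    list(ids = ids, Dm = dm, m = m,
         alone = setNames(alone, ids), combo = setNames(combo, ids))
  })
}

.score_stage <- function(cfg, truth, layout_fun, seed_base, tag) {
  ids <- names(truth$alone)
  lay_alone <- layout_fun(paste0(tag, "_alone"), ids)
  lay_combo <- layout_fun(paste0(tag, "_combo"), ids,
                          ptDrug = cfg$pt_drug,
                          ptConcentration = cfg$pt_concentration)
  sts <- list(alone = list(), combo = list())
  qc <- list()
  for (rep in 1:2) {
    rd_a <- simulateScreenPlate(lay_alone, truth$alone, cfg$ctrl_signal,
                                cfg$cv, seed = seed_base + rep,
                                replicateId = paste0("r", rep))
    rd_c <- simulateScreenPlate(lay_combo, truth$combo, cfg$ctrl_signal,
                                cfg$cv, seed = seed_base + 10 + rep,
                                replicateId = paste0("r", rep))
    sts$alone[[rep]] <- normalizePlate(rd_a, lay_alone)
    sts$combo[[rep]] <- normalizePlate(rd_c, lay_combo)
    qc[[length(qc) + 1L]] <- zPrime(rd_a, lay_alone, cfg$z_threshold)
    qc[[length(qc) + 1L]] <- zPrime(rd_c, lay_combo, cfg$z_threshold)
  }
  hits <- callHits(compoundScores(sts$alone), compoundScores(sts$combo),
                   ruleVariant = cfg$rule_variant, ptDrugId = cfg$pt_drug,
                   ptConcentration = cfg$pt_concentration)
  list(hits = hits, qc = do.call(rbind, qc), scoreTables = sts)
}

.stage_file <- function(cfg, name) file.path(cfg$out_dir, name)

.require_artifact <- function(cfg, name, stage) {
  f <- .stage_file(cfg, name)
  if (!file.exists(f))
    stop(sprintf("orchestration error: stage '%s' needs missing artifact %s",
                 stage, f))
  read.csv(f, stringsAsFactors = FALSE)
}

#' Run the screening / synergy pipeline
#'
#' Executes the selected stages of the four-stage workflow on synthetic data
#' with known ground truth: (1) primary screen -- duplicate library and
#' library+Pt plates are simulated, normalized, QC'd and hit combinations
#' called; (2) confirmation -- hits are re-tested on an edge-free layout with
#' fresh noise; (3) synergy quantification -- each confirmed hit is taken
#' through a constant-ratio dose-response design and the full
#' combination-index analysis; (4) HCA -- the top synergistic pair is
#' validated on simulated object tables.  Every stage writes CSV outputs into
#' \code{out_dir}; a JSON manifest records seeds, configuration and QC.
#' Given the same configuration the run is deterministic, and stages can be
#' re-run individually against the CSVs of earlier stages.
#'
#' @param config a \code{\link{pipelineConfig}} (or a YAML path).
#' @return the manifest, invisibly, as a list.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readPipelineConfig(config)
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  truth <- .screen_truth(cfg)
  agents <- setNames(
    lapply(seq_along(truth$ids),
           function(i) AgentModel(truth$ids[i], truth$Dm[i], truth$m[i])),
    truth$ids)
  pt_agent <- AgentModel(cfg$pt_drug, cfg$pt_dm, cfg$pt_m)
  manifest <- list(package = "PlateSynergy",
                   version = as.character(packageVersion("PlateSynergy")),
                   seed = cfg$seed, stages = cfg$stages,
                   config = unclass(cfg)[setdiff(names(cfg), "out_dir")])
  qc_all <- list()

  if ("screen" %in% cfg$stages) {
    st <- .score_stage(cfg, truth, primaryScreenLayout, cfg$seed * 100L,
                       "primary")
    write.csv(st$hits, .stage_file(cfg, "hit_calls_full.csv"),
              row.names = FALSE)
    write.csv(st$hits[st$hits$is_hit, , drop = FALSE],
              .stage_file(cfg, "hits.csv"), row.names = FALSE)
    for (i in seq_along(st$scoreTables$alone)) {
      writeScoreTable(st$scoreTables$alone[[i]],
                      .stage_file(cfg, sprintf("scores_primary_alone_r%d.csv", i)))
      writeScoreTable(st$scoreTables$combo[[i]],
                      .stage_file(cfg, sprintf("scores_primary_combo_r%d.csv", i)))
    }
    qc_all$screen <- st$qc
    manifest$screen <- list(n_hits = sum(st$hits$is_hit))
  }

  if ("confirm" %in% cfg$stages) {
    hits <- .require_artifact(cfg, "hits.csv", "confirm")
    if (nrow(hits)) {
      keep <- truth$ids %in% hits$compound_id
      sub <- list(ids = truth$ids[keep],
                  alone = truth$alone[keep], combo = truth$combo[keep])
      st <- .score_stage(cfg, sub, confirmationLayout, cfg$seed * 100L + 50L,
                         "confirm")
      confirmed <- st$hits[st$hits$is_hit, , drop = FALSE]
      qc_all$confirm <- st$qc
    } else {
      confirmed <- hits
    }
    write.csv(confirmed, .stage_file(cfg, "confirmed_hits.csv"),
              row.names = FALSE)
    manifest$confirm <- list(n_confirmed = nrow(confirmed))
  }

  if ("synergy" %in% cfg$stages) {
    confirmed <- .require_artifact(cfg, "confirmed_hits.csv", "synergy")
    take <- utils::head(order(confirmed$mean_combo - confirmed$mean_alone,
                              decreasing = TRUE), cfg$max_synergy)
    rows <- list()
    for (k in seq_along(take)) {
      id <- confirmed$compound_id[take[k]]
      tc <- if (id %in% names(cfg$planted)) cfg$planted[[id]] else NULL
      spec <- if (is.null(tc)) interactionSpec("loewe_additive") else
        interactionSpec("fixed_ci", targetCI = tc)
      sim <- simulateConstantRatio(pt_agent, agents[[id]], spec,
                                   nRep = cfg$n_rep, cv = cfg$cv,
                                   seed = cfg$seed * 1000L + k * 7L)
      res <- tryCatch(
        analyzeCombination(sim$drA, sim$drB, sim$drMix,
                           rThreshold = cfg$r_threshold,
                           effectLevels = cfg$effect_levels),
        error = function(e) NULL)
      rows[[k]] <- if (is.null(res))
        data.frame(pt_drug = cfg$pt_drug, compound_id = id, ratio = NA,
                   ci50 = NA, ci75 = NA, ci90 = NA, ci95 = NA,
                   ci75_hw = NA, ci90_hw = NA, ci_wt = NA,
                   grade = "analysis failed", synergistic = NA,
                   true_ci = if (is.null(tc)) 1 else tc)
      else {
        ci <- res@ciAt$ci[match(c(0.5, 0.75, 0.9, 0.95), res@ciAt$fa)]
        ## a synergy call requires the grade to be supported by the S.D.A.
        ## variability: 95% intervals below 1 at the 75% and 90% levels
        sda <- res@sda[res@sda$fa %in% c(0.75, 0.9), ]
        supported <- nrow(sda) == 2 &&
          all(sda$mean + sda$halfwidth < 1)
        data.frame(pt_drug = cfg$pt_drug, compound_id = id,
                   ratio = res@design@ratioLabel,
                   ci50 = ci[1], ci75 = ci[2], ci90 = ci[3], ci95 = ci[4],
                   ci75_hw = sda$halfwidth[sda$fa == 0.75],
                   ci90_hw = sda$halfwidth[sda$fa == 0.9],
                   ci_wt = ciWt(res), grade = gradeSymbol(res),
                   synergistic = grepl("+", gradeSymbol(res), fixed = TRUE) &&
                     supported,
                   true_ci = if (is.null(tc)) 1 else tc)
      }
    }
    syn <- do.call(rbind, rows)
    write.csv(syn, .stage_file(cfg, "synergy.csv"), row.names = FALSE)
    manifest$synergy <- list(n_analyzed = nrow(syn),
                             n_synergistic = sum(syn$synergistic %in% TRUE))
  }

  if ("hca" %in% cfg$stages) {
    syn <- .require_artifact(cfg, "synergy.csv", "hca")
    top <- syn[order(syn$ci_wt), ][1, ]
    rows <- list()
    for (tp in c(24, 48, 72)) {
      ## dead fraction grows with exposure time and with synergy
      grow <- tp / 72
      cells <- list(control = c(live = 400, dead = 8),
                    drug_a = c(live = 240, dead = round(60 * grow) + 8),
                    drug_b = c(live = 260, dead = round(50 * grow) + 8),
                    combo = c(live = 120,
                              dead = round(180 * grow / max(top$ci_wt, 0.2)) + 8))
      for (cond in names(cells)) {
        tab <- simulateHCAObjects(cells[[cond]]["live"],
                                  cells[[cond]]["dead"],
                                  seed = cfg$seed * 10L + tp +
                                    match(cond, names(cells)),
                                  well = "B3", timepoint = tp)
        m <- wellMetrics(tab)
        m$condition <- cond
        rows[[length(rows) + 1L]] <- m
      }
    }
    met <- do.call(rbind, rows)
    ctrl <- met[met$condition == "control", ]
    norm <- normalizeToControl(met[met$condition != "control", ], ctrl)
    flags <- combinationFlags(norm[norm$condition == "drug_a", ],
                              norm[norm$condition == "drug_b", ],
                              norm[norm$condition == "combo", ])
    write.csv(norm, .stage_file(cfg, "hca_metrics.csv"), row.names = FALSE)
    write.csv(flags, .stage_file(cfg, "hca_flags.csv"), row.names = FALSE)
    manifest$hca <- list(pair = top$compound_id,
                         n_supra = sum(flags$supra_single_agent))
  }

  if (length(qc_all)) {
    qc_df <- do.call(rbind, qc_all)
    write.csv(qc_df, .stage_file(cfg, "qc.csv"), row.names = FALSE)
    manifest$qc <- list(n_plates = nrow(qc_df), n_pass = sum(qc_df$pass))
  }
  js <- jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA)
  manifest$config_hash <- sprintf("%08x",
    sum(as.integer(charToRaw(as.character(js))) *
        (seq_along(charToRaw(as.character(js))) %% 97 + 1)) %% .Machine$integer.max)
  jsonlite::write_json(manifest, .stage_file(cfg, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
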