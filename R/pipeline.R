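default_config <- function() {
  list(
    mode = "synthetic",
    synthetic = list(n_genomes = 12L, gc_min = 0.25, gc_max = 0.70,
                     n_genes = 100L, mean_length = 150, dispersion = 10,
                     persistence = 0, coil_gc_coupling = 0),
    inputs = NULL,              # files mode: manifest TSV + optional cog_table
    do_structure = TRUE,
    do_regressions = TRUE,
    do_cog = FALSE,
    cog = list(n_cogs = 8L, members = 40L, coil_slope = 0, noise = 0.02),
    align_cogs = FALSE,
    cp_thresholds = c(0.6, 0.9, 1.1, 1.4),
    cog_min_members = 10L,
    p_threshold = 0.001,
    regression_degree = 1,
    seed = 1L,
    outdir = "gc2struct_out")
}

#' Read and validate a pipeline run configuration
#'
#' Configurations are plain YAML `key: value` files mirroring the
#' arguments of [run_pipeline()]. Unset keys take the documented
#' defaults. Exactly one of the synthetic block (`mode: synthetic`) or the
#' real-input block (`mode: files` with `inputs.manifest`) may be active.
#'
#' @param path Path to a YAML config file.
#' @return A validated config list of class `"run_config"`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(default_config(), user)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  if (!cfg$mode %in% c("synthetic", "files")) {
    stop("mode must be 'synthetic' or 'files'")
  }
  if (cfg$mode == "files" && is.null(cfg$inputs$manifest)) {
    stop("files mode needs inputs: manifest: <organisms TSV>")
  }
  if (cfg$mode == "synthetic" && !is.null(cfg$inputs)) {
    stop("exactly one of the synthetic spec or real inputs may be active")
  }
  if (length(cfg$cp_thresholds) != 4L || any(diff(cfg$cp_thresholds) <= 0)) {
    stop("cp_thresholds must be 4 increasing values")
  }
  if (cfg$p_threshold <= 0 || cfg$p_threshold >= 1) {
    stop("p_threshold must lie in (0, 1)")
  }
  class(cfg) <- c("run_config", "list")
  cfg
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

load_genomes_from_manifest <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    stop("organism manifest not found: ", manifest_path)
  }
  man <- utils::read.delim(manifest_path, stringsAsFactors = FALSE)
  need <- c("organism_id", "genes_fasta", "proteins_fasta")
  if (!all(need %in% names(man))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "),
         " (optional: ss_fasta, taxon_label)")
  }
  base <- dirname(manifest_path)
  resolve <- function(p) ifelse(file.exists(p), p, file.path(base, p))
  lapply(seq_len(nrow(man)), function(i) {
    genes <- read_fasta(resolve(man$genes_fasta[i]), "nucleotide")
    prots <- read_fasta(resolve(man$proteins_fasta[i]), "protein")
    ss <- NULL
    if ("ss_fasta" %in% names(man) && !is.na(man$ss_fasta[i]) &&
        nzchar(man$ss_fasta[i])) {
      ss <- read_fasta(resolve(man$ss_fasta[i]), "ss")
    }
    genome_record(man$organism_id[i], genes, prots, ss,
                  taxon_label = if ("taxon_label" %in% names(man)) {
                    man$taxon_label[i]
                  } else {
                    NA_character_
                  })
  })
}

#' Run the whole GC-structure analysis pipeline
#'
#' Executes the stages in order - load or generate genomes; coding GC and
#' amino-acid composition; per-structure statistics and conformational
#' parameters; GC regressions; COG analysis - and writes one TSV per
#' result table plus a JSON run manifest into `outdir`. Structure stages
#' are skipped with a warning for organisms lacking H/E/C annotations.
#' Reruns with an identical configuration and seed are byte-identical.
#'
#' @param config A config list / `"run_config"` (see [read_run_config()]),
#'   or the path to a YAML config file.
#' @param outdir Output directory (created if needed); overrides the
#'   config's `outdir`.
#' @param seed Overrides the config's seed.
#' @return Invisibly, a list with the in-memory tables and the output
#'   paths.
#' @export
run_pipeline <- function(config = list(), outdir = NULL, seed = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) {
    config <- validate_config(utils::modifyList(default_config(), config))
  }
  if (!is.null(outdir)) config$outdir <- outdir
  if (!is.null(seed)) config$seed <- as.integer(seed)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0L)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # -- stage: load / generate ---------------------------------------------
  genomes <- stage("load", {
    if (config$mode == "synthetic") {
      sy <- config$synthetic
      gcs <- if (sy$n_genomes == 1L) {
        (sy$gc_min + sy$gc_max) / 2
      } else {
        seq(sy$gc_min, sy$gc_max, length.out = sy$n_genomes)
      }
      lapply(seq_along(gcs), function(i) {
        prop <- if (sy$coil_gc_coupling != 0) {
          gc_coupled_propensity(gcs[i], coupling = sy$coil_gc_coupling)
        } else {
          default_propensity()
        }
        generate_genome(synthetic_spec(
          target_gc = gcs[i], n_genes = sy$n_genes,
          mean_length = sy$mean_length, dispersion = sy$dispersion,
          propensity = prop, persistence = sy$persistence,
          seed = config$seed + i))$record
      })
    } else {
      load_genomes_from_manifest(config$inputs$manifest)
    }
  })

  # -- stage: composition --------------------------------------------------
  res <- list(config = config)
  stage("composition", {
    res$codon_classes <- classify_amino_acids()
    paths["codon_classes"] <- write_tsv(res$codon_classes,
                                         file.path(outdir,
                                                   "codon_classes.tsv"))
    res$gc_table <- data.frame(
      organism_id = vapply(genomes, function(g) g$organism_id, ""),
      taxon_label = vapply(genomes, function(g) g$taxon_label, ""),
      coding_gc = vapply(genomes, compute_coding_gc, 0),
      stringsAsFactors = FALSE)
    paths["gc_table"] <- write_tsv(res$gc_table,
                                    file.path(outdir, "gc_table.tsv"))
    freqs <- lapply(genomes, function(g) aa_frequencies(g)$frequency)
    aa_wide <- do.call(rbind, freqs)
    colnames(aa_wide) <- AA20
    res$aa_freq <- data.frame(organism_id = res$gc_table$organism_id,
                              aa_wide, stringsAsFactors = FALSE)
    paths["aa_freq"] <- write_tsv(res$aa_freq,
                                   file.path(outdir, "aa_freq.tsv"))
  })

  # -- stage: structure ----------------------------------------------------
  annotated <- vapply(genomes, function(g) {
    inherits(g$proteome, "annotated_proteome") && length(g$proteome$ss) > 0L
  }, TRUE)
  if (config$do_structure && !any(annotated)) {
    warning("no organism carries H/E/C annotations; structure stages skipped")
  }
  if (config$do_structure && any(annotated)) {
    stage("structure", {
      gsub <- genomes[annotated]
      cp_rows <- lapply(gsub, function(g) {
        cpars <- conformational_params(g)
        data.frame(organism_id = g$organism_id,
                   aa = rep(AA20, times = 3L),
                   ss = rep(SS3, each = 20L),
                   count = as.vector(cpars$counts),
                   f_ss_aa = as.vector(cpars$f_ss_aa),
                   f_ss = rep(unname(cpars$f_ss), each = 20L),
                   cp = as.vector(cpars$cp),
                   stringsAsFactors = FALSE)
      })
      res$cp_table <- do.call(rbind, cp_rows)
      paths["cp_table"] <- write_tsv(res$cp_table,
                                      file.path(outdir, "cp_table.tsv"))
      comp <- do.call(rbind, lapply(gsub, function(g) {
        data.frame(organism_id = g$organism_id, ss_composition(g),
                   stringsAsFactors = FALSE)
      }))
      res$ss_composition <- comp
      paths["ss_composition"] <- write_tsv(comp,
                                            file.path(outdir,
                                                      "ss_composition.tsv"))
    })
  }

  # -- stage: regressions --------------------------------------------------
  if (config$do_regressions && nrow(res$gc_table) >= 3L) {
    stage("regressions", {
      gc <- res$gc_table$coding_gc
      deg <- config$regression_degree
      one_fit <- function(id, y) {
        ft <- fit_gc_trend(gc[match(names(y), res$gc_table$organism_id)],
                           unname(y), degree = deg)
        # slopes reported per GC percent to match conventional tables
        data.frame(response = id, n = ft$n, slope_per_gc_pct = ft$slope / 100,
                   intercept = ft$intercept, p_value = ft$p_value,
                   r_squared = ft$r_squared, signif = ft$signif_code,
                   degree = ft$degree, stringsAsFactors = FALSE)
      }
      rows <- list()
      for (a in AA20) {
        y <- stats::setNames(res$aa_freq[[a]], res$aa_freq$organism_id)
        rows[[paste0("aafreq_", a)]] <- one_fit(paste0("aafreq_", a), y)
      }
      if (!is.null(res$ss_composition)) {
        for (st in c("helix", "sheet", "coil")) {
          y <- stats::setNames(res$ss_composition[[st]],
                               res$ss_composition$organism_id)
          rows[[paste0("sscomp_", st)]] <- one_fit(paste0("sscomp_", st), y)
        }
        cpt <- res$cp_table
        for (a in AA20) {
          for (st in SS3) {
            sel <- cpt$aa == a & cpt$ss == st & !is.na(cpt$cp)
            if (sum(sel) >= 3L) {
              y <- stats::setNames(cpt$cp[sel], cpt$organism_id[sel])
              id <- paste0("cp_", a, "_", st)
              rows[[id]] <- one_fit(id, y)
            }
          }
        }
      }
      res$regressions <- do.call(rbind, c(rows, make.row.names = FALSE))
      paths["regressions"] <- write_tsv(res$regressions,
                                         file.path(outdir,
                                                   "regressions.tsv"))
    })
  }

  # -- stage: cog ----------------------------------------------------------
  run_cog <- config$do_cog || (config$mode == "files" &&
                                 !is.null(config$inputs$cog_table))
  if (run_cog) {
    stage("cog", {
      groups <- if (config$mode == "files" &&
                    !is.null(config$inputs$cog_table)) {
        memb <- read_cog_table(config$inputs$cog_table)
        build_cog_groups(memb, genomes)
      } else {
        co <- config$cog
        generate_cog_set(n_cogs = co$n_cogs, members = co$members,
                         coil_slope = co$coil_slope, noise = co$noise,
                         seed = config$seed + 10000L)
      }
      calls <- lapply(groups, function(g) {
        g2 <- tryCatch(select_representatives(g), error = function(e) NULL)
        if (is.null(g2) || nrow(g2$members) < config$cog_min_members) {
          return(NULL)
        }
        call_cog_bias(g2, p_threshold = config$p_threshold,
                      min_members = config$cog_min_members)
      })
      calls <- Filter(Negate(is.null), calls)
      if (length(calls)) {
        res$cog_bias <- do.call(rbind, lapply(calls, function(cl) {
          data.frame(cog_id = cl$cog_id, n = cl$n,
                     slope_helix = cl$slopes[["helix"]],
                     slope_sheet = cl$slopes[["sheet"]],
                     slope_coil = cl$slopes[["coil"]],
                     p_helix = cl$p_values[["helix"]],
                     p_sheet = cl$p_values[["sheet"]],
                     p_coil = cl$p_values[["coil"]],
                     biased = cl$biased, stringsAsFactors = FALSE)
        }))
        rownames(res$cog_bias) <- NULL
        paths["cog_bias"] <- write_tsv(res$cog_bias,
                                        file.path(outdir, "cog_bias.tsv"))
      }
      if (isTRUE(config$align_cogs)) {
        adir <- file.path(outdir, "alignments")
        dir.create(adir, showWarnings = FALSE)
        for (g in groups) {
          g2 <- tryCatch(select_representatives(g), error = function(e) NULL)
          if (!is.null(g2) && "ss" %in% names(g2$members) &&
              nrow(g2$members) >= 2L) {
            aln <- align_ss(g2)
            write_ss_alignment(aln, file.path(adir,
                                              paste0(g2$cog_id, ".afa")))
          }
        }
      }
    })
  }

  # -- manifest ------------------------------------------------------------
  resolved <- file.path(outdir, "config.yaml")
  cfg_plain <- unclass(config)
  yaml::write_yaml(cfg_plain, resolved)
  manifest <- list(
    package = "gc2struct",
    version = as.character(utils::packageVersion("gc2struct")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(resolved)),
    outputs = as.list(vapply(paths, function(p) {
      unname(tools::md5sum(p))
    }, "")))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  res$paths <- c(paths, config = resolved,
                 manifest = file.path(outdir, "manifest.json"))
  invisible(res)
}
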