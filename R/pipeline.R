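#' Read a two-column chromosome sizes table
#' @param path TSV with chromosome name and length (no header).
#' @return Named integer vector.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.delim(path, header = FALSE, col.names = c("chrom", "size"))
  stats::setNames(as.integer(df$size), df$chrom)
}

#' Write labeled motif hits as BED6+1
#'
#' Columns: chrom, start (0-based), end, label, score (bits), strand,
#' p-value.
#'
#' @param gr [GenomicRanges::GRanges] with \code{label}, \code{score},
#'   \code{p_value} columns.
#' @param path Output path.
#' @export
write_hits_bed <- function(gr, path) {
  out <- data.frame(as.character(GenomicRanges::seqnames(gr)),
                    GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr),
                    gr$label, gr$score, as.character(GenomicRanges::strand(gr)),
                    gr$p_value)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read labeled motif hits (BED6+1, as written by [write_hits_bed()])
#' @param path Input path.
#' @return [GenomicRanges::GRanges] with \code{label}, \code{score},
#'   \code{p_value}.
#' @export
read_hits_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED",
                            extraCols = c(p_value = "numeric"))
  gr$label <- gr$name
  gr$name <- NULL
  gr
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

default_run_config <- function() {
  list(
    pool_fasta = NULL, width = 19, max_motifs = 5, e_max = 1e-5,
    p_assign = 1e-4, min_remaining = 0.05, min_assigned = 20, seed = 1,
    track_bedgraph = NULL, input_bedgraph = NULL, sites_bed = NULL,
    chrom_sizes = NULL, flank = 1500, bin = 20,
    query_bed = NULL, feature_bed = NULL, control_bed = NULL,
    tss_bed = NULL, link_window = 50000,
    meth_sites_bed = NULL, meth_tsv = NULL, rad21_bed = NULL, smc3_bed = NULL,
    reads_bed = NULL, motif_position = 12, n_boot = 1000,
    loops_tsv = NULL, fragments_fasta = NULL, loop_tag = NULL, n_bags = 1000
  )
}

#' Run the composed analysis pipeline
#'
#' Executes the stages whose inputs are configured: motif discovery on the
#' pooled FASTA, signal fold-enrichment, colocalization enrichment, gene
#' linking, methylation/cohesin analysis, and loop tagging with the bagged
#' correlation. Every stage writes its tabular output under \code{out_dir};
#' a single \code{summary.json} records the full parameter set and the key
#' numbers of each executed stage. A failing stage aborts with an error
#' naming the stage; outputs of earlier stages are retained.
#'
#' @param config Named list (unknown keys are rejected) or path to a YAML
#'   file; see \code{motifdiv:::default_run_config()} for the keys and
#'   defaults.
#' @param out_dir Output directory (created if needed).
#' @return The summary list, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  base <- default_run_config()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(base, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(params = cfg[!vapply(cfg, is.null, TRUE)])
  fit <- NULL

  if (!is.null(cfg$pool_fasta)) {
    fit <- pipeline_stage("discover", {
      pool <- read_fasta(cfg$pool_fasta)
      f <- discover_motifs(pool, width = cfg$width, max_motifs = cfg$max_motifs,
                           e_max = cfg$e_max, p_assign = cfg$p_assign,
                           min_remaining = cfg$min_remaining,
                           min_assigned = cfg$min_assigned, seed = cfg$seed)
      write_meme(f$motifs, file.path(out_dir, "motifs.meme.txt"))
      utils::write.table(f$partition, file.path(out_dir, "partition.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(f$log, file.path(out_dir, "discovery_log.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      f
    })
    summary$discovery <- list(
      n_motifs = length(fit$motifs),
      labels = vapply(fit$motifs, `[[`, "", "label"),
      e_values = vapply(fit$motifs, `[[`, 1.0, "e_value"),
      q_values = vapply(fit$motifs, `[[`, 1.0, "q_value"),
      n_assigned = vapply(fit$motifs, `[[`, 1L, "n_assigned"),
      unassigned = sum(fit$partition$motif == "unassigned"),
      stop_reason = fit$stop_reason
    )
  }

  if (!is.null(cfg$track_bedgraph) && !is.null(cfg$input_bedgraph) &&
      !is.null(cfg$sites_bed) && !is.null(cfg$chrom_sizes)) {
    summary$signal <- pipeline_stage("enrich-signal", {
      sites <- read_bed(cfg$sites_bed)
      sizes <- read_chrom_sizes(cfg$chrom_sizes)
      sm <- bin_signal(sites, read_bedgraph(cfg$track_bedgraph), sizes,
                       flank = cfg$flank, bin = cfg$bin)
      ctrl <- control_profile(sites, read_bedgraph(cfg$input_bedgraph), sizes,
                              flank = cfg$flank, bin = cfg$bin)
      fe <- fold_enrichment(sm, ctrl)
      utils::write.table(cbind(site = rownames(fe), as.data.frame(fe)),
                         file.path(out_dir, "fold_enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      central <- abs(sm$offsets) <= 5 * cfg$bin
      list(n_sites = nrow(fe), n_bins = ncol(fe),
           central_mean_fold = mean(fe[, central], na.rm = TRUE))
    })
  }

  if (!is.null(cfg$query_bed) && !is.null(cfg$feature_bed) && !is.null(cfg$control_bed)) {
    summary$colocalization <- pipeline_stage("enrich-coloc", {
      res <- colocalization_fold(read_bed(cfg$query_bed),
                                 read_bed(cfg$feature_bed),
                                 read_bed(cfg$control_bed))
      unclass(res)
    })
  }

  if (!is.null(cfg$tss_bed) && !is.null(cfg$sites_bed)) {
    summary$gene_links <- pipeline_stage("link-genes", {
      links <- link_genes(read_bed(cfg$tss_bed), read_hits_bed(cfg$sites_bed),
                          window = cfg$link_window)
      utils::write.table(links, file.path(out_dir, "gene_links.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      as.list(table(links$label))
    })
  }

  if (!is.null(cfg$meth_sites_bed) && !is.null(cfg$meth_tsv)) {
    summary$methylation <- pipeline_stage("methylation", {
      sites <- read_hits_bed(cfg$meth_sites_bed)
      meth <- read_methylation(cfg$meth_tsv)
      lev <- methylation_at_position(sites, meth, motif_position = cfg$motif_position)
      cls <- classify_methylation(lev)
      ann <- data.frame(site = seq_along(sites), label = sites$label,
                        level = lev, methyl_class = cls)
      utils::write.table(ann, file.path(out_dir, "methylation_sites.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      out <- list(n_sites = length(sites),
                  n_methylated = sum(cls == "methylated"),
                  n_unmethylated = sum(cls == "unmethylated"),
                  n_unknown = sum(cls == "unknown"))
      if (!is.null(cfg$rad21_bed) && !is.null(cfg$smc3_bed)) {
        coh <- cohesin_sites(read_bed(cfg$rad21_bed), read_bed(cfg$smc3_bed))
        dep <- cohesin_depletion_test(sites, sites[cls == "methylated"], coh)
        out$cohesin <- dep
      }
      if (!is.null(cfg$reads_bed)) {
        counts <- binding_intensity(sites, read_bed(cfg$reads_bed))
        cc <- methylation_signal_correlation(lev, counts, n_boot = cfg$n_boot,
                                             seed = cfg$seed)
        out$level_signal_correlation <- cc
      }
      out
    })
  }

  if (!is.null(cfg$loops_tsv) && !is.null(cfg$fragments_fasta) && !is.null(fit)) {
    summary$loops <- pipeline_stage("loops", {
      loops <- read_loops(cfg$loops_tsv)
      frags <- read_fasta(cfg$fragments_fasta)
      tagged <- tag_fragments(frags, fit, p_threshold = cfg$p_assign)
      utils::write.table(tagged, file.path(out_dir, "fragment_tags.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      tags <- setdiff(unique(tagged$tag), "untagged")
      enr <- lapply(tags, function(tg) {
        e <- loop_fold_enrichment(tagged, loops, tg)
        list(tag = tg, fold = e$fold, p_value = e$p_value, n_tag = e$n_tag)
      })
      out <- list(n_fragments = nrow(tagged), n_looped = sum(loops$looped),
                  enrichment = enr)
      tag0 <- if (is.null(cfg$loop_tag)) tags[1L] else cfg$loop_tag
      if (length(tag0)) {
        feature <- as.numeric(tagged$tag[match(loops$distal, tagged$fragment)] == tag0)
        pcc <- bagged_pcc(feature, loops$looped, n_bags = cfg$n_bags, seed = cfg$seed)
        utils::write.table(data.frame(bag = seq_along(pcc$values), r = pcc$values),
                           file.path(out_dir, "bagged_pcc.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        out$bagged_pcc <- list(tag = tag0, mean = pcc$mean,
                               ci_low = pcc$ci[1], ci_high = pcc$ci[2],
                               n_positive = pcc$n_positive)
      }
      out
    })
  }

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

cli_opt <- function(...) optparse::make_option(...)

cli_specs <- function(cmd) {
  switch(cmd,
    discover = list(
      cli_opt("--fasta", type = "character"),
      cli_opt("--width", type = "integer", default = 19),
      cli_opt("--max-motifs", type = "integer", default = 5, dest = "max_motifs"),
      cli_opt("--e-max", type = "double", default = 1e-5, dest = "e_max"),
      cli_opt("--p-assign", type = "double", default = 1e-4, dest = "p_assign"),
      cli_opt("--min-remaining", type = "double", default = 0.05, dest = "min_remaining"),
      cli_opt("--seed", type = "integer", default = 1),
      cli_opt("--out-prefix", type = "character", default = "run", dest = "out_prefix")),
    scan = list(
      cli_opt("--fasta", type = "character"),
      cli_opt("--motifs", type = "character"),
      cli_opt("--p-threshold", type = "double", default = 1e-4, dest = "p_threshold"),
      cli_opt("--out", type = "character", default = "hits.tsv")),
    simulate = list(
      cli_opt("--what", type = "character", default = "pool"),
      cli_opt("--n", type = "integer", default = 1000),
      cli_opt("--seed", type = "integer", default = 1),
      cli_opt("--out", type = "character", default = ".")),
    run = list(
      cli_opt("--config", type = "character"),
      cli_opt("--out", type = "character", default = "pipeline_out")),
    stop("unknown subcommand: ", cmd)
  )
}

#' Command-line entry point
#'
#' Thin dispatcher behind the \code{inst/cli/motifdiv.R} script. Subcommands:
#' \code{discover}, \code{scan}, \code{simulate}, \code{run}. Every
#' invocation logs its full parameter set to a JSON file next to its outputs.
#'
#' @param args Character vector of command-line arguments (default:
#'   \code{commandArgs(trailingOnly = TRUE)}).
#' @return Exit status (0 on success), invisibly.
#' @export
motifdiv_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    message("usage: motifdiv <discover|scan|simulate|run> [options]")
    return(invisible(1L))
  }
  cmd <- args[1L]
  status <- tryCatch({
    opts <- optparse::parse_args(
      optparse::OptionParser(option_list = cli_specs(cmd)), args[-1L])
    if (cmd == "discover") {
      if (is.null(opts$fasta)) stop("--fasta is required")
      fit <- discover_motifs(opts$fasta, width = opts$width,
                             max_motifs = opts$max_motifs, e_max = opts$e_max,
                             p_assign = opts$p_assign,
                             min_remaining = opts$min_remaining, seed = opts$seed)
      write_meme(fit$motifs, paste0(opts$out_prefix, ".meme.txt"))
      utils::write.table(fit$partition, paste0(opts$out_prefix, ".partition.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(list(params = opts, log = fit$log),
                           paste0(opts$out_prefix, ".log.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    } else if (cmd == "scan") {
      if (is.null(opts$fasta) || is.null(opts$motifs)) stop("--fasta and --motifs are required")
      motifs <- read_meme(opts$motifs)
      seqs <- read_fasta(opts$fasta)
      fit <- structure(list(motifs = motifs,
                            params = list(p_assign = opts$p_threshold)),
                       class = "motif_discovery")
      hits <- predict(fit, seqs, p_threshold = opts$p_threshold)
      utils::write.table(hits, opts$out, sep = "\t", quote = FALSE, row.names = FALSE)
    } else if (cmd == "simulate") {
      dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
      if (opts$what == "pool") {
        sim <- simulate_motif_pool(n_sequences = opts$n, seed = opts$seed)
        write_fasta(sim$sequences, file.path(opts$out, "pool.fa"))
        utils::write.table(sim$truth, file.path(opts$out, "pool_truth.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      } else if (opts$what == "loops") {
        sim <- simulate_loop_fixture(seed = opts$seed)
        write_loops(sim$loops, file.path(opts$out, "loops.tsv"))
        write_fasta(sim$sequences, file.path(opts$out, "fragments.fa"))
      } else stop("unknown --what: ", opts$what)
      jsonlite::write_json(opts, file.path(opts$out, "simulate_params.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    } else if (cmd == "run") {
      if (is.null(opts$config)) stop("--config is required")
      run_pipeline(opts$config, opts$out)
    }
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
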