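#' Assemble a pipeline configuration
#'
#' Flat key/value configuration for \code{\link{runPipeline}}. Defaults run
#' the bundled atlas with the default three-group simulation design and all
#' pairwise comparisons.
#'
#' @param ... configuration overrides; see Details.
#' @details Keys: \code{atlas_path} (NULL = bundled atlas),
#'   \code{cohort_path} (NULL = simulate), \code{simulation} (list with
#'   \code{master_seed} and \code{groups}, each group a list of
#'   \code{name}, \code{n_subjects}, \code{lambda}, optional \code{blocks},
#'   \code{mean_suvr}, \code{noise_sd}; NULL = default design),
#'   \code{negative_rule}, \code{threshold}, \code{fisher_z},
#'   \code{measures} (NULL = all 16), \code{comparisons} (list of
#'   2-vectors, or \code{"all"} for every pair), \code{n_permutations},
#'   \code{alpha}, \code{gamma}, \code{restarts}, \code{fwe_method},
#'   \code{seed}, \code{output_dir}, \code{timestamp}.
#' @return named list.
#' @export
pipelineConfig <- function(...) {
    cfg <- list(atlas_path = NULL, cohort_path = NULL, simulation = NULL,
        negative_rule = "zero", threshold = 0, fisher_z = FALSE,
        measures = NULL, comparisons = "all", n_permutations = 1000L,
        alpha = 0.05, gamma = 1, restarts = 100L, fwe_method = "maxstat",
        seed = 1L, output_dir = "fdgnet_out", timestamp = TRUE)
    over <- list(...)
    bad <- setdiff(names(over), names(cfg))
    if (length(bad) > 0)
        stop("unknown config key(s): ", paste(bad, collapse = ", "))
    utils::modifyList(cfg, over)
}

#' Read a pipeline configuration file
#'
#' YAML file with the flat keys of \code{\link{pipelineConfig}}; unknown
#' keys are rejected.
#'
#' @param path YAML config path.
#' @return named list.
#' @export
readPipelineConfig <- function(path) {
    if (!file.exists(path)) stop("config file not found: ", path)
    do.call(pipelineConfig, yaml::read_yaml(path))
}

design_from_config <- function(cfg, atlas) {
    if (is.null(cfg$simulation))
        return(defaultDesign(atlas, masterSeed = cfg$seed))
    sim <- cfg$simulation
    profiles <- lapply(sim$groups, function(g)
        groupProfile(g$name, g$n_subjects, lambda = unlist(g$lambda),
            blocks = g$blocks,
            meanSuvr = if (is.null(g$mean_suvr)) 1.2 else g$mean_suvr,
            noiseSd = if (is.null(g$noise_sd)) 0.1 else g$noise_sd))
    simulationDesign(atlas, profiles,
        masterSeed = if (is.null(sim$master_seed)) cfg$seed else
            sim$master_seed)
}

stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    value <- tryCatch(expr, error = function(e)
        stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
    list(value = value, seconds = proc.time()[["elapsed"]] - t0)
}

#' Run the full metabolic-network pipeline
#'
#' Load (or simulate) the cohort, split by group, build each group's
#' correlation matrix and connectivity graph, compute global and nodal
#' measures, run the configured permutation comparisons, and write every
#' output as delimited text with a provenance comment header. Re-running an
#' identical config and seed reproduces every numerical output exactly.
#'
#' @param config a \code{\link{pipelineConfig}} list or path to a YAML
#'   config file.
#' @return run report (list): versions, seed, config hash, group sizes,
#'   output paths, per-stage wall times. Invisibly.
#' @export
runPipeline <- function(config = pipelineConfig()) {
    if (is.character(config)) config <- readPipelineConfig(config)
    cfg <- do.call(pipelineConfig, config)  # validate keys, fill defaults
    uni <- measure_universe()
    if (!is.null(cfg$measures)) {
        bad <- setdiff(cfg$measures, c(uni$global, uni$nodal))
        if (length(bad) > 0)
            stop("config validation: unknown measure name(s): ",
                paste(bad, collapse = ", "))
    }
    if (!cfg$negative_rule %in% c("zero", "absolute"))
        stop("config validation: negative_rule must be zero or absolute")
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    # hash only the keys that determine the numbers, not where they land
    sci <- cfg[setdiff(names(cfg), c("output_dir", "timestamp"))]
    hdr <- provenance_header(cfg$seed, sci, timestamp = cfg$timestamp)
    times <- list()
    report <- list(package = "FDGnet",
        version = as.character(utils::packageVersion("FDGnet")),
        r_version = paste(R.version$major, R.version$minor, sep = "."),
        seed = cfg$seed, config_hash = config_hash(sci))

    st <- stage("load_atlas", {
        if (is.null(cfg$atlas_path)) readAtlas(dk68AtlasFile())
        else readAtlas(cfg$atlas_path)
    })
    at <- st$value; times$load_atlas <- st$seconds

    st <- stage("load_cohort", {
        if (!is.null(cfg$cohort_path)) readCohort(cfg$cohort_path, at)
        else simulateCohort(design_from_config(cfg, at))
    })
    cohort <- st$value; times$load_cohort <- st$seconds

    st <- stage("split", splitByGroup(cohort))
    groups <- st$value; times$split <- st$seconds
    report$n_subjects <- ncol(cohort)
    report$group_sizes <- vapply(groups, ncol, 0L)

    outputs <- character(0)
    gm <- list()
    st <- stage("measures", {
        for (g in names(groups)) {
            corr <- correlationMatrix(groups[[g]])
            graph <- toGraph(corr, negativeRule = cfg$negative_rule,
                threshold = cfg$threshold, fisherZ = cfg$fisher_z)
            cp <- file.path(cfg$output_dir,
                paste0("correlation_", g, ".tsv"))
            writeMatrix(corValues(corr), cp, seed = cfg$seed,
                timestamp = cfg$timestamp)
            ap <- file.path(cfg$output_dir, paste0("adjacency_", g, ".tsv"))
            writeMatrix(graphWeights(graph), ap, seed = cfg$seed,
                timestamp = cfg$timestamp)
            nod <- nodalMeasures(graph)
            np <- file.path(cfg$output_dir, paste0("nodal_", g, ".tsv"))
            write_delim_with_header(nod, np, hdr)
            bn <- exportBrainNet(graph, nod,
                file = file.path(cfg$output_dir, paste0("network_", g)))
            gm[[g]] <- globalMeasures(graph, gamma = cfg$gamma,
                seed = derive_seed(cfg$seed, match(g, names(groups))),
                restarts = cfg$restarts)
            outputs <- c(outputs, cp, ap, np, bn)
        }
        gdf <- data.frame(group = names(gm),
            do.call(rbind, gm), row.names = NULL, check.names = FALSE)
        gp <- file.path(cfg$output_dir, "global_measures.tsv")
        write_delim_with_header(gdf, gp, hdr)
        outputs <- c(outputs, gp)
        gdf
    })
    globalTable <- st$value; times$measures <- st$seconds

    comparisons <- cfg$comparisons
    if (identical(comparisons, "all")) {
        nm <- names(groups)
        comparisons <- if (length(nm) < 2) list() else
            utils::combn(nm, 2, simplify = FALSE)
    }
    results <- list()
    if (length(comparisons) > 0) {
        st <- stage("compare", {
            for (cmp in comparisons) {
                a <- cmp[[1]]; b <- cmp[[2]]
                if (!all(c(a, b) %in% names(groups)))
                    stop("unknown group in comparison: ",
                        paste(cmp, collapse = " vs "))
                res <- permutationTest(groups[[a]], groups[[b]],
                    nPermutations = cfg$n_permutations, alpha = cfg$alpha,
                    seed = cfg$seed, measures = cfg$measures,
                    gamma = cfg$gamma, restarts = cfg$restarts,
                    fweMethod = cfg$fwe_method,
                    negativeRule = cfg$negative_rule,
                    threshold = cfg$threshold)
                tag <- paste0(a, "_vs_", b)
                for (part in c("global", "nodal")) {
                    df <- slot(res, part)
                    if (nrow(df) == 0) next
                    pp <- file.path(cfg$output_dir,
                        paste0("comparison_", tag, "_", part, ".tsv"))
                    write_delim_with_header(df, pp, hdr)
                    outputs <- c(outputs, pp)
                }
                sig <- summarizeComparison(res)
                sig[] <- lapply(sig, function(x)
                    if (is.numeric(x)) round(x, 4) else x)
                sp <- file.path(cfg$output_dir,
                    paste0("significant_", tag, ".tsv"))
                write_delim_with_header(sig, sp, hdr)
                outputs <- c(outputs, sp)
                results[[tag]] <- res
            }
            results
        })
        results <- st$value; times$compare <- st$seconds
    }

    report$global_measures <- globalTable
    report$comparisons <- results
    report$outputs <- outputs
    report$stage_seconds <- times
    invisible(report)
}
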