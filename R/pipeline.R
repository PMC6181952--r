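#' @importFrom jsonlite write_json
#' @importFrom yaml read_yaml
NULL

# internal: accept a config as a list, or a path to a YAML/JSON file
.loadConfig <- function(config) {
    if (is.character(config) && length(config) == 1L) {
        if (!file.exists(config)) stop("config file not found: ", config)
        if (grepl("\\.json$", config))
            return(jsonlite::read_json(config, simplifyVector = TRUE))
        return(yaml::read_yaml(config))
    }
    if (!is.list(config)) stop("config must be a list or a file path")
    config
}

# internal: materialize one cohort entry (an ExpressionCohort, or a
# list(path, dialect, platform, clinical)) and normalize it to log2
.loadCohort <- function(entry, ncfg) {
    if (is(entry, "ExpressionCohort")) {
        ds <- entry
    } else if (is.list(entry) && !is.null(entry$path)) {
        if (!file.exists(entry$path))
            stop("missing input file: ", entry$path)
        ds <- readExpressionTable(entry$path,
                                  dialect = entry$dialect %||% "plain_tsv",
                                  datasetId = entry$id %||% NULL)
        if (!is.null(entry$clinical)) {
            if (!file.exists(entry$clinical))
                stop("missing input file: ", entry$clinical)
            clin <- readClinicalTable(entry$clinical)
            cd <- S4Vectors::DataFrame(
                clin[match(colnames(ds), clin$sample_id), , drop = FALSE],
                row.names = colnames(ds))
            SummarizedExperiment::colData(ds) <- cd
        }
    } else stop("unrecognized cohort entry")
    platform <- if (is.list(entry)) entry$platform %||% "array"
                else "array"
    if (exprScale(ds) == "raw_intensity")
        ds <- normalizeCohort(ds, ncfg, platform = platform)
    ds
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# internal: echo every threshold in force into the report
.configEcho <- function(crit, ncfg, extra = list()) {
    c(list(screen_criteria = unclass(crit),
           normalization = unclass(ncfg)), extra)
}

#' Run the multi-cohort candidate screen
#'
#' Stage 1 normalizes each cohort and screens the candidate list for
#' consistent anchor correlation and tumor-versus-normal alteration.
#' When a perturbation experiment is supplied, stage 2 runs the
#' moderated-t differential expression, selects fold-change-filtered
#' candidate genes, and re-screens those genes for correlation
#' consistency against the stage-1 winner (the top selected gene), the
#' downstream-effector step of the workflow.
#'
#' @param config a list or YAML/JSON path with elements:
#'   \code{cohorts} (list of [ExpressionCohort-class] objects or
#'   \code{list(path, dialect, clinical, platform)} entries),
#'   \code{probe_map} (data.frame or TSV path), \code{anchor},
#'   \code{candidates} (character vector or file with one gene per
#'   line), optional \code{criteria} / \code{normalize} argument lists,
#'   and optional \code{stage2} with \code{ds} (or \code{path} /
#'   \code{dialect}), \code{groups}, and \code{de_criteria}.
#' @return List of class \code{"ScreenReport"}: \code{config_echo},
#'   \code{correlations}, \code{alterations}, \code{verdicts},
#'   \code{selected}, and (when requested) \code{stage2} with the DE
#'   table, selections, and the effector consistency verdicts.
#' @export
runCandidateScreen <- function(config) {
    config <- .loadConfig(config)
    crit <- do.call(screenCriteria, config$criteria %||% list())
    ncfg <- do.call(normalizationConfig, config$normalize %||% list())
    map <- config$probe_map
    if (is.character(map)) map <- readProbeMap(map)
    missing_files <- character()
    for (entry in config$cohorts)
        if (is.list(entry) && !is.null(entry$path)) {
            if (!file.exists(entry$path))
                missing_files <- c(missing_files, entry$path)
            if (!is.null(entry$clinical) && !file.exists(entry$clinical))
                missing_files <- c(missing_files, entry$clinical)
        }
    if (length(missing_files))
        stop("missing input file(s): ",
             paste(missing_files, collapse = ", "))
    cohorts <- lapply(config$cohorts, .loadCohort, ncfg = ncfg)
    candidates <- config$candidates
    if (is.character(candidates) && length(candidates) == 1L &&
        file.exists(candidates))
        candidates <- readLines(candidates, warn = FALSE)
    corr <- correlateWithAnchor(cohorts, map, config$anchor, candidates,
                                crit)
    alt <- tumorVsNormal(cohorts, map, candidates, crit)
    verdicts <- aggregateScreen(corr, alt, crit)
    report <- list(config_echo = .configEcho(crit, ncfg,
                       list(anchor = config$anchor,
                            n_cohorts = length(cohorts),
                            n_candidates = length(candidates))),
                   correlations = corr, alterations = alt,
                   verdicts = verdicts,
                   selected = verdicts$gene[verdicts$selected])
    if (!is.null(config$stage2)) {
        s2 <- config$stage2
        ds2 <- if (!is.null(s2$ds)) s2$ds
               else readExpressionTable(s2$path,
                                        dialect = s2$dialect %||%
                                            "probe_profile")
        if (exprScale(ds2) == "raw_intensity")
            ds2 <- normalizeCohort(ds2, ncfg)
        else if (!is.null(detectionP(ds2)))
            ds2 <- detectionFilter(ds2, ncfg)
        map2 <- s2$probe_map %||% map
        if (is.character(map2)) map2 <- readProbeMap(map2)
        de <- runModeratedDE(ds2, s2$groups, map = map2)
        decrit <- do.call(deSelectionCriteria, s2$de_criteria %||% list())
        sel <- selectDECandidates(de, decrit)
        winner <- s2$winner %||% report$selected[1L]
        stage2 <- list(de = de, selection = sel,
                       de_criteria = unclass(decrit), winner = winner)
        if (length(sel$candidate_genes) && !is.na(winner) &&
            length(winner)) {
            c2 <- correlateWithAnchor(cohorts, map, winner,
                                      sel$candidate_genes, crit)
            if (nrow(c2)) {
                agg <- do.call(rbind, lapply(unique(c2$gene),
                    function(g) {
                        i <- c2$gene == g
                        data.frame(gene = g, n_evaluable = sum(i),
                                   n_pass = sum(c2$passes[i]),
                                   stringsAsFactors = FALSE)
                    }))
                agg$consistent <- agg$n_pass >
                    crit$consistency_fraction * agg$n_evaluable
                agg <- agg[order(-(agg$n_pass / agg$n_evaluable),
                                 agg$gene), , drop = FALSE]
                stage2$correlations <- c2
                stage2$effector_verdicts <- agg
                stage2$consistent_effectors <-
                    agg$gene[agg$consistent]
            }
        }
        report$stage2 <- stage2
    }
    class(report) <- "ScreenReport"
    report
}

#' Evaluate single-gene and composite prognostic signatures
#'
#' For each cohort carrying survival annotation, runs the Q1-vs-rest
#' disease-free-survival stratification for every gene individually and
#' for the mean-signal composite of the full gene list, and tabulates
#' chi-square, p, O/E hazard ratio, and group sizes side by side.
#' Cohorts without survival columns are skipped with a warning.
#'
#' @param config list or YAML/JSON path with \code{cohorts},
#'   \code{probe_map}, \code{genes}, optional \code{stratification}
#'   (argument list for [stratificationConfig()]) and \code{normalize}.
#' @return List of class \code{"ScreenReport"} with
#'   \code{config_echo}, \code{stratification} (the side-by-side
#'   data.frame), and \code{details} (per-cohort
#'   \code{"DFSStratification"} objects).
#' @export
runSignatureEvaluation <- function(config) {
    config <- .loadConfig(config)
    scfg <- do.call(stratificationConfig,
                    config$stratification %||% list())
    ncfg <- do.call(normalizationConfig, config$normalize %||% list())
    map <- config$probe_map
    if (is.character(map)) map <- readProbeMap(map)
    cohorts <- lapply(config$cohorts, .loadCohort, ncfg = ncfg)
    genes <- config$genes
    rows <- list(); details <- list()
    for (ds in cohorts) {
        cd <- SummarizedExperiment::colData(ds)
        if (!all(c("dfs_time", "dfs_event") %in% colnames(cd))) {
            warning("cohort '", datasetId(ds),
                    "' has no survival annotation; skipped")
            next
        }
        sigs <- c(as.list(genes),
                  if (length(genes) > 1L) list(genes))
        for (gs in sigs) {
            label <- if (length(gs) > 1L)
                paste0("composite(", paste(gs, collapse = "+"), ")")
                else gs
            st <- tryCatch(stratifyDFS(ds, map, gs, scfg),
                           error = function(e) NULL)
            if (is.null(st)) next
            lr <- st$logrank
            rows[[length(rows) + 1L]] <- data.frame(
                dataset_id = datasetId(ds), signature = label,
                n_q1 = st$n_q1, n_rest = st$n_rest,
                chi_sq = if (is.null(lr)) NA_real_ else lr$chi_sq,
                p_value = if (is.null(lr)) NA_real_ else lr$p_value,
                hazard_ratio = if (is.null(lr)) NA_real_
                               else lr$hazard_ratio,
                stringsAsFactors = FALSE)
            details[[paste(datasetId(ds), label, sep = ":")]] <- st
        }
    }
    report <- list(config_echo = list(
                       stratification = unclass(scfg),
                       normalization = unclass(ncfg),
                       genes = genes),
                   stratification = if (length(rows))
                       do.call(rbind, rows) else NULL,
                   details = details)
    class(report) <- "ScreenReport"
    report
}

#' Write a screen report to disk as TSV + JSON
#'
#' Emits \code{config.json} (the threshold echo) plus one TSV per
#' table present: \code{correlations.tsv}, \code{alterations.tsv},
#' \code{verdicts.tsv}, \code{de.tsv}, \code{effector_verdicts.tsv},
#' \code{stratification.tsv}.
#'
#' @param report a \code{"ScreenReport"}.
#' @param dir output directory (created if absent).
#' @return \code{dir}, invisibly.
#' @export
writeScreenReport <- function(report, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report$config_echo,
                         file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    wt <- function(tab, name) if (!is.null(tab) &&
                                  NROW(tab) >= 0)
        utils::write.table(tab, file.path(dir, name), sep = "\t",
                           quote = FALSE, row.names = FALSE)
    wt(report$correlations, "correlations.tsv")
    wt(report$alterations, "alterations.tsv")
    wt(report$verdicts, "verdicts.tsv")
    wt(report$stratification, "stratification.tsv")
    if (!is.null(report$stage2)) {
        wt(as.data.frame(report$stage2$de), "de.tsv")
        wt(report$stage2$effector_verdicts, "effector_verdicts.tsv")
    }
    invisible(dir)
}

#' @export
print.ScreenReport <- function(x, ...) {
    cat("ScreenReport\n")
    if (!is.null(x$verdicts)) {
        cat(sprintf("  candidates screened: %d; selected: %s\n",
                    nrow(x$verdicts),
                    if (length(x$selected))
                        paste(x$selected, collapse = ", ")
                    else "(none)"))
    }
    if (!is.null(x$stage2))
        cat(sprintf(
            "  stage 2: %d significant probes, %d fold-change probes, %d candidate genes\n",
            length(x$stage2$selection$significant),
            length(x$stage2$selection$fc_filtered),
            length(x$stage2$selection$candidate_genes)))
    if (!is.null(x$stratification)) {
        cat("  stratification results:\n")
        print(x$stratification, row.names = FALSE)
    }
    invisible(x)
}
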