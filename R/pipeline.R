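#' @include conformational-pca.R domain-geometry.R ion-sites.R
NULL

.default_selections <- list(
  grk5_small_lobe = "A:1-32,180-270,490-510",
  grk5_large_lobe = "A:271-450",
  grk5_kinase_domain = "A:1-32,180-510",
  p_loop = "A:190-200")

#' Validate and normalise a pipeline configuration
#'
#' Reads a YAML configuration (or takes an equivalent list), fills
#' documented defaults, checks every cross-reference and aggregates
#' all errors into one message.  Overlapping residue intervals within
#' a selection are merged with a warning; duplicate structure ids are
#' an error.  Selection presets for the GRK5 domain layout
#' (`grk5_small_lobe`, `grk5_large_lobe`, `grk5_kinase_domain`,
#' `p_loop`) are predefined and can be overridden.
#'
#' @param config path to a YAML file or a list.
#' @return the normalised configuration (list with class
#'   `"kscapeConfig"`).
#' @export
validateConfig <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  errs <- character(0)
  if (is.null(cfg$structures) || !length(cfg$structures))
    errs <- c(errs, "config must list at least one structure")
  ids <- vapply(cfg$structures, function(s)
    if (is.null(s$id)) NA_character_ else s$id, character(1))
  if (anyNA(ids)) errs <- c(errs, "every structure needs an id")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    errs <- c(errs, paste("duplicate structure id(s):",
                          paste(dup, collapse = ", ")))
  for (s in cfg$structures)
    if (is.null(s$path))
      errs <- c(errs, paste0("structure ", s$id,
                             ": a local 'path' is required (accessions are ",
                             "not downloaded)"))
  selTexts <- utils::modifyList(.default_selections,
                                as.list(cfg$selections))
  selections <- list()
  for (nm in names(selTexts)) {
    sel <- tryCatch(parseSelection(selTexts[[nm]]),
                    error = function(e) e)
    if (inherits(sel, "error")) {
      errs <- c(errs, paste0("selection ", nm, ": ",
                             conditionMessage(sel)))
    } else {
      raw <- selTexts[[nm]]
      # warn when normalisation merged overlapping intervals
      nIn <- length(strsplit(sub("^[^:]*:", "", raw), ",")[[1]])
      if (nrow(sel@ranges) > 0 && nIn > nrow(sel@ranges))
        warning("selection ", nm,
                ": overlapping intervals merged during normalisation")
      selections[[nm]] <- sel
    }
  }
  checkSel <- function(nm, where) {
    if (!is.null(nm) && !nm %in% names(selections))
      errs <<- c(errs, paste0(where, ": unknown selection ",
                              sQuote(nm)))
  }
  checkId <- function(id, where) {
    if (!is.null(id) && !id %in% ids)
      errs <<- c(errs, paste0(where, ": unknown structure id ",
                              sQuote(id)))
  }
  if (!is.null(cfg$ensemble)) {
    e <- cfg$ensemble
    for (m in e$members) checkId(m, "ensemble members")
    if (is.null(e$reference)) cfg$ensemble$reference <- e$members[[1]]
    else checkId(e$reference, "ensemble reference")
    if (is.null(e$correspondence))
      cfg$ensemble$correspondence <- "by_number"
    if (!cfg$ensemble$correspondence %in% c("by_number", "by_alignment"))
      errs <- c(errs, "ensemble correspondence must be by_number or by_alignment")
    checkSel(e$selection, "ensemble selection")
    if (!is.null(e$lobes))
      for (l in e$lobes) checkSel(l, "ensemble lobes")
  }
  for (i in seq_along(cfg$comparisons)) {
    cmp <- cfg$comparisons[[i]]
    where <- paste0("comparison ", i)
    checkId(cmp$a, where); checkId(cmp$b, where)
    checkSel(cmp$align, where); checkSel(cmp$moving, where)
  }
  for (id in cfg$ion_scan) checkId(id, "ion_scan")
  if (is.null(cfg$output_dir)) cfg$output_dir <- "kinasescape-out"
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (length(errs))
    stop("invalid configuration:\n  - ",
         paste(errs, collapse = "\n  - "), call. = FALSE)
  cfg$selections <- selections
  cfg$structure_ids <- ids
  class(cfg) <- "kscapeConfig"
  cfg
}

.openness_scores <- function(structures, members, selections, lobes) {
  if (is.null(lobes) || length(lobes) != 2) return(NULL)
  s1 <- selections[[lobes[[1]]]]
  s2 <- selections[[lobes[[2]]]]
  vapply(members, function(id) {
    a1 <- selectAtoms(structures[[id]], s1)
    a2 <- selectAtoms(structures[[id]], s2)
    if (nrow(a1) == 0 || nrow(a2) == 0) return(NA_real_)
    sqrt(sum((colMeans(a1[, c("x", "y", "z")]) -
              colMeans(a2[, c("x", "y", "z")]))^2))
  }, numeric(1))
}

#' Run the structure-comparison pipeline
#'
#' Executes, as configured: ensemble PCA of the kinase-domain core
#' (with projections of every member), pairwise comparisons (global
#' Calpha RMSD, interlobe rotation, optional interhelix-angle change
#' and residue-pair distance deltas) and ion-site scans.  Per-task
#' failures are recorded in the report without aborting the remaining
#' tasks.  Outputs are deterministic given the config and inputs:
#' `projections.csv`, `comparisons.csv`, `ion_sites.csv`, and
#' `report.json` in `output_dir`.
#'
#' @param config a path to a YAML config, a list, or a validated
#'   `kscapeConfig`.
#' @param quiet suppress per-task log lines.
#' @return the run report (list with class `"kscapeReport"`),
#'   invisibly; its `errors` element is an empty list on full success.
#' @export
runPipeline <- function(config, quiet = FALSE) {
  cfg <- if (inherits(config, "kscapeConfig")) config else
    validateConfig(config)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  log <- function(...) if (!quiet) message(...)
  report <- list(errors = list(),
                 provenance = list(
                   package = as.character(utils::packageVersion("KinaseScape")),
                   r_version = R.version.string,
                   seed = cfg$seed))
  fail <- function(task, e) {
    report$errors[[task]] <<- conditionMessage(e)
    log("  [error] ", task, ": ", conditionMessage(e))
  }
  structures <- list()
  for (s in cfg$structures) {
    st <- tryCatch(readStructure(s$path, id = s$id),
                   error = function(e) e)
    if (inherits(st, "error")) fail(paste0("read:", s$id), st)
    else {
      structures[[s$id]] <- st
      log("read ", s$id, ": ", nAtoms(st), " atoms")
    }
  }

  if (!is.null(cfg$ensemble)) {
    e <- cfg$ensemble
    res <- tryCatch({
      members <- unlist(e$members)
      sel <- if (is.null(e$selection)) atomSelection() else
        cfg$selections[[e$selection]]
      core <- buildEnsembleCore(structures[members], sel,
                                mode = e$correspondence,
                                referenceId = e$reference)
      mat <- alignEnsemble(core, structures[members])
      open <- .openness_scores(structures, members, cfg$selections,
                               e$lobes)
      model <- fitConformationPCA(mat, openness = open)
      sc <- scores(model)[, seq_len(min(4L, ncol(scores(model)))),
                          drop = FALSE]
      proj <- data.frame(structure_id = members, round(sc, 6),
                         row.names = NULL)
      names(proj)[-1] <- tolower(colnames(sc))
      utils::write.csv(proj, file.path(cfg$output_dir,
                                       "projections.csv"),
                       row.names = FALSE)
      report$pca <- list(core_size = nrow(meanCoords(model)),
                         variances = variances(model),
                         significant_modes = significantModes(model),
                         projections = proj)
      log("ensemble PCA: core ", nrow(meanCoords(model)),
          " residues, ", significantModes(model),
          " significant mode(s)")
      model
    }, error = function(er) { fail("ensemble_pca", er); NULL })
    report$model <- res
  }

  cmpRows <- list()
  for (i in seq_along(cfg$comparisons)) {
    cmp <- cfg$comparisons[[i]]
    task <- paste0("compare:", cmp$a, ":", cmp$b)
    row <- tryCatch({
      a <- structures[[cmp$a]]; b <- structures[[cmp$b]]
      allSel <- atomSelection()
      core <- matchCoreByNumber(a, b, allSel)
      sup <- superposeStructures(a, b, core)
      out <- list(a = cmp$a, b = cmp$b,
                  rmsd_global = rmsd(sup$result),
                  n_atoms = nAtoms(sup$result),
                  interlobe_angle = NA_real_,
                  axis_x = NA_real_, axis_y = NA_real_,
                  axis_z = NA_real_, interhelix_delta = NA_real_)
      if (!is.null(cmp$align) && !is.null(cmp$moving)) {
        rot <- interlobeRotation(a, b, cfg$selections[[cmp$align]],
                                 cfg$selections[[cmp$moving]])
        out$interlobe_angle <- rot@angle
        out$axis_x <- rot@axis[1]; out$axis_y <- rot@axis[2]
        out$axis_z <- rot@axis[3]
      }
      if (!is.null(cmp$helix_ranges)) {
        hr <- cmp$helix_ranges
        ch <- if (is.null(cmp$chain)) "A" else cmp$chain
        toRange <- function(x) {
          sel <- parseSelection(x)
          as.integer(sel@ranges[1, ])
        }
        out$interhelix_delta <- interhelixAngleChange(
          a, b, toRange(hr[[1]]), toRange(hr[[2]]), ch)
      }
      if (!is.null(cmp$pairs)) {
        deltas <- vapply(cmp$pairs, function(pr)
          pairDistance(a, pr[[1]], pr[[2]]) -
            pairDistance(b, pr[[1]], pr[[2]]), numeric(1))
        out$pair_distance_deltas <- paste(
          vapply(seq_along(deltas), function(j)
            sprintf("%s-%s:%.3f", cmp$pairs[[j]][[1]],
                    cmp$pairs[[j]][[2]], deltas[j]), character(1)),
          collapse = ";")
        report$pair_deltas[[task]] <- deltas
      }
      log(sprintf("%s: RMSD %.3f A over %d atoms%s", task,
                  out$rmsd_global, out$n_atoms,
                  if (!is.na(out$interlobe_angle))
                    sprintf(", interlobe %.2f deg", out$interlobe_angle)
                  else ""))
      out
    }, error = function(er) { fail(task, er); NULL })
    if (!is.null(row)) cmpRows[[length(cmpRows) + 1]] <- row
  }
  if (length(cmpRows)) {
    base <- c("a", "b", "rmsd_global", "n_atoms", "interlobe_angle",
              "axis_x", "axis_y", "axis_z", "interhelix_delta",
              "pair_distance_deltas")
    cmpDf <- do.call(rbind, lapply(cmpRows, function(r) {
      r <- r[intersect(base, names(r))]
      for (nm in setdiff(base, names(r))) r[[nm]] <- NA
      as.data.frame(r[base], stringsAsFactors = FALSE)
    }))
    utils::write.csv(cmpDf, file.path(cfg$output_dir,
                                      "comparisons.csv"),
                     row.names = FALSE)
    report$comparisons <- cmpDf
  }

  ionRows <- list()
  for (id in cfg$ion_scan) {
    res <- tryCatch({
      tab <- scanSolventSites(structures[[id]])
      if (nrow(tab)) cbind(structure_id = id, tab) else NULL
    }, error = function(er) { fail(paste0("ion_scan:", id), er); NULL })
    if (!is.null(res)) ionRows[[length(ionRows) + 1]] <- res
  }
  if (length(ionRows)) {
    ionDf <- do.call(rbind, ionRows)
    utils::write.csv(ionDf, file.path(cfg$output_dir, "ion_sites.csv"),
                     row.names = FALSE)
    report$ion_sites <- ionDf
  }

  json <- report
  json$model <- NULL       # S4 model not JSON-serialisable; see writePCAModel
  jsonlite::write_json(json, file.path(cfg$output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", force = TRUE)
  class(report) <- "kscapeReport"
  invisible(report)
}
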