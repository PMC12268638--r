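#' @include structure-io.R
NULL

.BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

.categorize_ligand <- function(lig) {
  ifelse(lig$resid %in% .WATER_RESID & lig$elesy == "O", "water_O",
  ifelse(lig$elety %in% c("O", "OXT") & lig$elesy == "O",
         "backbone_carbonyl_O",
  ifelse(lig$elesy == "O" & !lig$elety %in% .BACKBONE_ATOMS, "sidechain_O",
  ifelse(lig$elesy == "N" & lig$elety != "N", "sidechain_N", "other"))))
}

#' Coordination shell around a candidate ion centre
#'
#' Collects all oxygen and nitrogen atoms (protein or water) within
#' `cutoff` of the centre, excluding any atom sitting at the centre
#' itself, and categorises each ligand.  Hydrogens are ignored.
#'
#' @param s a non-empty [Structure-class].
#' @param center numeric(3) position in A.
#' @param cutoff shell radius in A (default 3.5, bounding first-shell
#'   O/N contacts of K+).
#' @return a [CoordinationShell-class]; an empty shell is allowed.
#' @export
coordinationShell <- function(s, center, cutoff = 3.5) {
  a <- atoms(s)
  if (nrow(a) == 0) stop("structure has no atoms")
  cand <- a[a$elesy %in% c("O", "N"), , drop = FALSE]
  if (nrow(cand) > 0) {
    d <- sqrt((cand$x - center[1])^2 + (cand$y - center[2])^2 +
              (cand$z - center[3])^2)
    keep <- d <= cutoff & d > 1e-6      # exclude the centre atom itself
    cand <- cand[keep, , drop = FALSE]
    d <- d[keep]
    o <- order(d)
    cand <- cand[o, , drop = FALSE]
    cand$distance <- d[o]
    cand$category <- .categorize_ligand(cand)
  } else {
    cand$distance <- numeric(0)
    cand$category <- character(0)
  }
  rownames(cand) <- NULL
  new("CoordinationShell", center = as.numeric(center), ligands = cand,
      cutoff = cutoff)
}

#' Default thresholds for geometric ion classification
#'
#' K+ and Na+ windows are anchored on their characteristic mean
#' metal-oxygen distances (about 2.8 and 2.4 A respectively) with the
#' boundary at 2.6 A; a central water can donate at most ~2 hydrogen
#' bonds, so >= 4 acceptor-only contacts rule water out.
#'
#' @return a named list of thresholds (distances in A).
#' @export
ionThresholds <- function() {
  list(k_cn_min = 5L, k_dist = c(2.6, 3.1),
       na_cn_min = 4L, na_dist = c(2.2, 2.6),
       acceptor_only_min = 4L, water_cn_max = 3L)
}

#' Classify a coordination shell as K+, Na+, water or unclassified
#'
#' Deterministic rule cascade on coordination number (CN) and mean
#' ligand distance:
#' \enumerate{
#'   \item CN >= 5 and mean distance in \[2.6, 3.1\] A: potassium;
#'   \item CN >= 4 and mean distance in \[2.2, 2.6) A: sodium;
#'   \item >= 4 acceptor-only contacts (backbone-carbonyl or water
#'     oxygens, which a central water would have to donate to):
#'     not water, but outside both ion windows -- unclassified;
#'   \item CN <= 3: water;
#'   \item otherwise unclassified.
#' }
#' The rationale string notes that refinement B-factor and difference-
#' density evidence is not assessed by this geometric classifier.
#'
#' @param shell a [CoordinationShell-class].
#' @param thresholds see [ionThresholds] (all configurable).
#' @return an [IonClassification-class].
#' @export
classifySite <- function(shell, thresholds = ionThresholds()) {
  lg <- ligands(shell)
  cn <- nrow(lg)
  md <- if (cn > 0) mean(lg$distance) else NA_real_
  acc <- if (cn > 0)
    sum(lg$category %in% c("backbone_carbonyl_O", "water_O")) else 0L
  th <- thresholds
  note <- paste("Geometric call only: refinement B-factors and",
                "difference density are not assessed.")
  if (cn == 0) {
    call <- "unclassified"
    rat <- "No ligands within the cutoff."
  } else if (cn >= th$k_cn_min && md >= th$k_dist[1] && md <= th$k_dist[2]) {
    call <- "potassium"
    rat <- sprintf(paste("CN %d with mean ligand distance %.2f A falls in",
                         "the K+ window [%.1f, %.1f] A."),
                   cn, md, th$k_dist[1], th$k_dist[2])
  } else if (cn >= th$na_cn_min && md >= th$na_dist[1] &&
             md < th$na_dist[2]) {
    call <- "sodium"
    rat <- sprintf(paste("CN %d with mean ligand distance %.2f A falls in",
                         "the Na+ window [%.1f, %.1f) A."),
                   cn, md, th$na_dist[1], th$na_dist[2])
  } else if (acc >= th$acceptor_only_min) {
    call <- "unclassified"
    rat <- sprintf(paste("%d acceptor-only contacts exclude water (a",
                         "central water would have to donate %d hydrogen",
                         "bonds), but the geometry (CN %d, mean %.2f A)",
                         "matches neither ion window."),
                   acc, acc, cn, md)
  } else if (cn <= th$water_cn_max) {
    call <- "water"
    rat <- sprintf("CN %d is compatible with an ordered water.", cn)
  } else {
    call <- "unclassified"
    rat <- sprintf("CN %d, mean %.2f A: no rule matched.", cn, md)
  }
  new("IonClassification", call = call,
      coordinationNumber = as.integer(cn), meanDistance = md,
      acceptorOnlyContacts = as.integer(acc),
      rationale = paste(rat, note))
}

.solvent_site_atoms <- function(a) {
  waterO <- a$resid %in% .WATER_RESID & a$elesy == "O"
  # monatomic ions: recognised element, residue consisting of one atom
  rkey <- paste(a$chain, a$resno, a$insert, a$resid, sep = "\r")
  singletons <- rkey %in% names(which(table(rkey) == 1))
  ion <- a$elesy %in% .ION_ELEMENTS & singletons &
    !(a$resid %in% .WATER_RESID)
  waterO | ion
}

#' Re-evaluate deposited waters and monatomic ions
#'
#' Every water oxygen and monatomic cation in the structure is passed
#' through [coordinationShell] and [classifySite]; results are sorted
#' by coordination number, descending, so buried high-CN sites (the
#' candidates worth re-modelling) come first.
#'
#' @param s a [Structure-class].
#' @param cutoff shell radius in A.
#' @param thresholds see [ionThresholds].
#' @return data.frame with one row per evaluated site: `siteId`,
#'   `resid`, `chain`, `resno`, `call`, `cn`, `meanDistance`,
#'   `acceptorOnly`; 0 rows when the structure has no solvent.
#' @export
scanSolventSites <- function(s, cutoff = 3.5,
                             thresholds = ionThresholds()) {
  a <- atoms(s)
  idx <- which(.solvent_site_atoms(a))
  if (!length(idx))
    return(data.frame(siteId = character(0), resid = character(0),
                      chain = character(0), resno = integer(0),
                      call = character(0), cn = integer(0),
                      meanDistance = numeric(0),
                      acceptorOnly = integer(0)))
  rows <- lapply(idx, function(i) {
    ctr <- c(a$x[i], a$y[i], a$z[i])
    cls <- classifySite(coordinationShell(s, ctr, cutoff), thresholds)
    data.frame(siteId = paste0(a$chain[i], ":", a$resid[i], ":",
                               a$resno[i], a$insert[i]),
               resid = a$resid[i], chain = a$chain[i], resno = a$resno[i],
               call = ionCall(cls), cn = coordinationNumber(cls),
               meanDistance = meanDistance(cls),
               acceptorOnly = cls@acceptorOnlyContacts,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$cn, out$siteId), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full report for one candidate ion site
#'
#' @param s a [Structure-class].
#' @param center numeric(3) site position in A.
#' @param cutoff shell radius in A.
#' @param thresholds see [ionThresholds].
#' @param path optional path; when given the report is also written as
#'   JSON.
#' @return a list (JSON-serialisable) with the site call, coordination
#'   number, mean ligand distance, per-ligand table (residue, atom,
#'   category, distance) and rationale.
#' @export
siteReport <- function(s, center, cutoff = 3.5,
                       thresholds = ionThresholds(), path = NULL) {
  shell <- coordinationShell(s, center, cutoff)
  cls <- classifySite(shell, thresholds)
  lg <- ligands(shell)
  rep <- list(
    center = as.numeric(center),
    cutoff = cutoff,
    call = ionCall(cls),
    coordination_number = coordinationNumber(cls),
    mean_distance = if (is.na(meanDistance(cls))) NULL else
      meanDistance(cls),
    acceptor_only_contacts = cls@acceptorOnlyContacts,
    ligands = if (nrow(lg)) data.frame(
      residue = paste0(lg$chain, ":", lg$resid, lg$resno, lg$insert),
      atom = lg$elety, category = lg$category,
      distance = lg$distance, stringsAsFactors = FALSE) else list(),
    rationale = if (coordinationNumber(cls) == 0)
      paste("unclassified, no ligands.", cls@rationale) else
      cls@rationale)
  if (!is.null(path))
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  rep
}
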