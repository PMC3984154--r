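#' Repeated point-count survey data
#'
#' Container for counts from repeated point-count surveys of a community of
#' species, together with site-level covariates. Counts are stored as an
#' `n_sites x n_species x n_visits` integer array; visits that were not
#' conducted at a site are recorded in `visit_mask` (a zero count is a
#' legitimate observation and is never used to encode a missing visit).
#'
#' @param counts integer array, dimension `n_sites x n_species x n_visits`.
#' @param site_covariates data frame or matrix of site covariates
#'   (`n_sites` rows), or `NULL` for a covariate-free survey.
#' @param visit_mask logical matrix `n_sites x n_visits`; `TRUE` where the
#'   visit was conducted. Defaults to all `TRUE`.
#' @param species_ids,site_ids character labels; default to dimnames of
#'   `counts` or generated labels.
#'
#' @return An object of class `survey_data` with elements `counts`,
#'   `site_covariates`, `visit_mask`, `species_ids`, `site_ids`.
#' @export
survey_data <- function(counts, site_covariates = NULL, visit_mask = NULL,
                        species_ids = NULL, site_ids = NULL) {
  if (length(dim(counts)) != 3L)
    stop("`counts` must be a 3-d array (sites x species x visits)")
  n <- dim(counts)[1L]; I <- dim(counts)[2L]; J <- dim(counts)[3L]
  if (is.null(visit_mask)) visit_mask <- matrix(TRUE, n, J)
  visit_mask <- as.matrix(visit_mask)
  if (!identical(dim(visit_mask), c(n, J)))
    stop("`visit_mask` must be ", n, " x ", J)
  if (is.null(species_ids))
    species_ids <- dimnames(counts)[[2L]] %||% paste0("sp", seq_len(I))
  if (is.null(site_ids))
    site_ids <- dimnames(counts)[[1L]] %||% paste0("site", seq_len(n))
  species_ids <- as.character(species_ids)
  site_ids <- as.character(site_ids)
  if (length(species_ids) != I) stop("length(species_ids) != n_species")
  if (length(site_ids) != n) stop("length(site_ids) != n_sites")
  obs <- aperm(array(visit_mask, c(n, J, I)), c(1L, 3L, 2L))
  vals <- counts[obs]
  bad <- which(!is.finite(vals) | vals < 0 | vals != round(vals))
  if (length(bad)) {
    idx <- which(obs)[bad[1L]]
    pos <- arrayInd(idx, c(n, I, J))
    stop(sprintf(
      "invalid count %s at site '%s', species '%s', visit %d (must be a nonnegative integer)",
      format(counts[idx]), site_ids[pos[1L]], species_ids[pos[2L]], pos[3L]))
  }
  counts[!obs] <- 0L
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(site_ids, species_ids, paste0("visit", seq_len(J)))
  Jk <- rowSums(visit_mask)
  if (any(Jk < 1))
    stop("site '", site_ids[which(Jk < 1)[1L]], "' has no surveyed visits")
  if (!any(Jk >= 2))
    warning("no site has >= 2 visits; detection probabilities are not estimable")
  if (!is.null(site_covariates)) {
    site_covariates <- as.data.frame(site_covariates)
    if (nrow(site_covariates) != n)
      stop("`site_covariates` must have one row per site")
    rownames(site_covariates) <- site_ids
  }
  structure(list(counts = counts, site_covariates = site_covariates,
                 visit_mask = visit_mask, species_ids = species_ids,
                 site_ids = site_ids),
            class = "survey_data")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.survey_data <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("survey_data: %d sites x %d species x up to %d visits\n",
              d[1L], d[2L], d[3L]))
  cat(sprintf("  surveyed visits: %d of %d site-visit cells\n",
              sum(x$visit_mask), length(x$visit_mask)))
  if (!is.null(x$site_covariates))
    cat("  site covariates:", paste(names(x$site_covariates), collapse = ", "), "\n")
  invisible(x)
}

#' Column-layout configuration for survey files
#'
#' Describes how a counts CSV encodes sites, visits, species and counts, so
#' that different file dialects (for example a supplementary table with one
#' column per species) can be read without code changes.
#'
#' @param format `"long"` (columns site, visit, species, count) or `"wide"`
#'   (columns site, visit, then one column per species).
#' @param site,visit,species,count column names used by the long format;
#'   `site` and `visit` are also used by the wide format.
#' @param species_cols for the wide format, the names of the per-species count
#'   columns, in species order; `NULL` means every column other than `site`
#'   and `visit`.
#' @param covariate_site name of the site-id column in the covariates file.
#' @return A list of class `survey_layout`.
#' @export
survey_layout <- function(format = c("long", "wide"), site = "site",
                          visit = "visit", species = "species",
                          count = "count", species_cols = NULL,
                          covariate_site = site) {
  format <- match.arg(format)
  structure(list(format = format, site = site, visit = visit,
                 species = species, count = count,
                 species_cols = species_cols, covariate_site = covariate_site),
            class = "survey_layout")
}

#' Read survey counts and site covariates from CSV files
#'
#' @param counts_path CSV file of counts, in the layout's long or wide format.
#' @param covariates_path CSV file of site covariates (one row per site), or
#'   `NULL`.
#' @param layout a [survey_layout()] describing the column mapping.
#' @return A validated [survey_data] object. Species order follows first
#'   appearance in the counts file (long format) or column order (wide
#'   format); site order follows first appearance.
#' @export
load_survey <- function(counts_path, covariates_path = NULL,
                        layout = survey_layout()) {
  if (!file.exists(counts_path)) stop("counts file not found: ", counts_path)
  raw <- read.csv(counts_path, check.names = FALSE, stringsAsFactors = FALSE)
  lay <- layout
  if (lay$format == "wide") {
    spc <- lay$species_cols %||% setdiff(names(raw), c(lay$site, lay$visit))
    missing_cols <- setdiff(c(lay$site, lay$visit, spc), names(raw))
    if (length(missing_cols))
      stop("counts file lacks column(s): ", paste(missing_cols, collapse = ", "))
    long <- data.frame(
      site = rep(as.character(raw[[lay$site]]), times = length(spc)),
      visit = rep(raw[[lay$visit]], times = length(spc)),
      species = rep(spc, each = nrow(raw)),
      count = unlist(raw[spc], use.names = FALSE),
      stringsAsFactors = FALSE)
    species_ids <- spc
  } else {
    missing_cols <- setdiff(c(lay$site, lay$visit, lay$species, lay$count),
                            names(raw))
    if (length(missing_cols))
      stop("counts file lacks column(s): ", paste(missing_cols, collapse = ", "))
    long <- data.frame(site = as.character(raw[[lay$site]]),
                       visit = raw[[lay$visit]],
                       species = as.character(raw[[lay$species]]),
                       count = raw[[lay$count]], stringsAsFactors = FALSE)
    species_ids <- unique(long$species)
  }
  bad <- which(!is.finite(long$count) | long$count < 0 |
                 long$count != round(long$count))
  if (length(bad)) {
    b <- bad[1L]
    stop(sprintf("invalid count '%s' (site '%s', species '%s', visit %s): counts must be nonnegative integers",
                 format(long$count[b]), long$site[b], long$species[b],
                 format(long$visit[b])))
  }
  site_ids <- unique(long$site)
  visit_ids <- sort(unique(long$visit))
  n <- length(site_ids); I <- length(species_ids); J <- length(visit_ids)
  counts <- array(0L, c(n, I, J))
  mask <- matrix(FALSE, n, J)
  ks <- match(long$site, site_ids)
  is_ <- match(long$species, species_ids)
  js <- match(long$visit, visit_ids)
  dup <- duplicated(cbind(ks, is_, js))
  if (any(dup))
    stop(sprintf("duplicate count record for site '%s', species '%s', visit %s",
                 long$site[dup][1L], long$species[dup][1L],
                 format(long$visit[dup][1L])))
  counts[cbind(ks, is_, js)] <- as.integer(long$count)
  mask[cbind(ks, js)] <- TRUE
  covs <- NULL
  if (!is.null(covariates_path)) {
    if (!file.exists(covariates_path))
      stop("covariates file not found: ", covariates_path)
    cv <- read.csv(covariates_path, check.names = FALSE,
                   stringsAsFactors = FALSE)
    if (!lay$covariate_site %in% names(cv))
      stop("covariates file lacks site column '", lay$covariate_site, "'")
    cv_sites <- as.character(cv[[lay$covariate_site]])
    diff1 <- setdiff(site_ids, cv_sites)
    diff2 <- setdiff(cv_sites, site_ids)
    if (length(diff1) || length(diff2))
      stop("site sets differ between counts and covariates files; ",
           "only in counts: {", paste(diff1, collapse = ", "), "}; ",
           "only in covariates: {", paste(diff2, collapse = ", "), "}")
    covs <- cv[match(site_ids, cv_sites), setdiff(names(cv), lay$covariate_site),
               drop = FALSE]
  }
  survey_data(counts, site_covariates = covs, visit_mask = mask,
              species_ids = species_ids, site_ids = site_ids)
}

#' Write survey counts and covariates to CSV files
#'
#' Inverse of [load_survey()]: only surveyed visits (per `visit_mask`) are
#' written, so a read/write round trip reproduces the data exactly.
#'
#' @param x a [survey_data] object.
#' @param counts_path,covariates_path output CSV paths (`covariates_path` may
#'   be `NULL` when there are no covariates).
#' @param layout a [survey_layout()]; both long and wide formats are supported.
#' @return `x`, invisibly.
#' @export
write_survey <- function(x, counts_path, covariates_path = NULL,
                         layout = survey_layout()) {
  stopifnot(inherits(x, "survey_data"))
  n <- length(x$site_ids); I <- length(x$species_ids)
  J <- dim(x$counts)[3L]
  lay <- layout
  kj <- which(x$visit_mask, arr.ind = TRUE)
  kj <- kj[order(kj[, 1L], kj[, 2L]), , drop = FALSE]
  if (lay$format == "wide") {
    wide <- data.frame(x$site_ids[kj[, 1L]], kj[, 2L],
                       stringsAsFactors = FALSE, check.names = FALSE)
    names(wide) <- c(lay$site, lay$visit)
    for (i in seq_len(I))
      wide[[x$species_ids[i]]] <- x$counts[cbind(kj[, 1L], i, kj[, 2L])]
    write.csv(wide, counts_path, row.names = FALSE, quote = FALSE)
  } else {
    long <- data.frame(
      rep(x$site_ids[kj[, 1L]], each = I),
      rep(kj[, 2L], each = I),
      rep(x$species_ids, times = nrow(kj)),
      as.vector(vapply(seq_len(nrow(kj)), function(r)
        x$counts[kj[r, 1L], , kj[r, 2L]], integer(I))),
      stringsAsFactors = FALSE)
    names(long) <- c(lay$site, lay$visit, lay$species, lay$count)
    write.csv(long, counts_path, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(covariates_path) && !is.null(x$site_covariates)) {
    cv <- cbind(setNames(data.frame(x$site_ids, stringsAsFactors = FALSE),
                         lay$covariate_site),
                x$site_covariates)
    write.csv(cv, covariates_path, row.names = FALSE, quote = FALSE)
  }
  invisible(x)
}

#' Species-level metadata: traits, guilds, detection covariates
#'
#' @param traits numeric matrix `n_species x Q` of morphological traits
#'   (rownames are species ids).
#' @param guild character or factor of guild labels, length `n_species`.
#' @param detect_covariates numeric matrix `n_species x M` of species-level
#'   detection covariates (for example sound power output in mW), or `NULL`.
#' @return An object of class `species_meta`.
#' @export
species_meta <- function(traits, guild = NULL, detect_covariates = NULL) {
  traits <- as.matrix(traits)
  if (!is.numeric(traits)) stop("`traits` must be numeric")
  I <- nrow(traits)
  miss <- which(!is.finite(traits), arr.ind = TRUE)
  if (nrow(miss) > 0L) {
    stop(sprintf("missing trait value for species '%s', trait '%s'",
                 rownames(traits)[miss[1L, 1L]] %||% miss[1L, 1L],
                 colnames(traits)[miss[1L, 2L]] %||% miss[1L, 2L]))
  }
  if (is.null(guild)) guild <- rep("all", I)
  guild <- as.character(guild)
  if (length(guild) != I) stop("`guild` must have one label per species")
  if (anyNA(guild)) stop("guild labels must partition the species (NA found)")
  if (!is.null(detect_covariates)) {
    detect_covariates <- as.matrix(detect_covariates)
    if (nrow(detect_covariates) != I)
      stop("`detect_covariates` must have one row per species")
    if (any(!is.finite(detect_covariates)))
      stop("missing detection-covariate value for species '",
           rownames(traits)[which(rowSums(!is.finite(detect_covariates)) > 0)[1L]],
           "'")
  }
  structure(list(traits = traits, guild = guild,
                 detect_covariates = detect_covariates),
            class = "species_meta")
}

#' @export
print.species_meta <- function(x, ...) {
  cat(sprintf("species_meta: %d species, %d traits (%s), %d guild(s)\n",
              nrow(x$traits), ncol(x$traits),
              paste(colnames(x$traits), collapse = ", "),
              length(unique(x$guild))))
  invisible(x)
}

#' Read species traits, guilds and detection covariates from CSV
#'
#' The traits file holds one row per species with a species-id column and one
#' numeric column per trait; the guilds file holds the guild label and any
#' species-level detection covariates. Both files may be the same file. Rows
#' are reordered to `species_order` (the order of the survey data).
#'
#' @param traits_path,guilds_path CSV paths (may be identical).
#' @param species_order character vector of species ids from the survey data.
#' @param species_col,guild_col column names.
#' @param trait_cols,detect_cols column name vectors; `NULL` means all numeric
#'   columns other than id/guild columns (and, for `detect_cols`, no columns).
#' @return A [species_meta] object with rows in `species_order`.
#' @export
load_species_meta <- function(traits_path, guilds_path = traits_path,
                              species_order,
                              species_col = "species", guild_col = "guild",
                              trait_cols = NULL, detect_cols = NULL) {
  tr <- read.csv(traits_path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!species_col %in% names(tr))
    stop("traits file lacks species column '", species_col, "'")
  ids <- as.character(tr[[species_col]])
  if (anyDuplicated(ids))
    stop("duplicate species label '", ids[duplicated(ids)][1L],
         "' in traits file")
  miss <- setdiff(species_order, ids)
  if (length(miss))
    stop("traits file missing species: ", paste(miss, collapse = ", "))
  if (is.null(trait_cols)) {
    cand <- setdiff(names(tr), c(species_col, guild_col, detect_cols))
    trait_cols <- cand[vapply(tr[cand], is.numeric, logical(1L))]
  }
  ord <- match(species_order, ids)
  traits <- as.matrix(tr[ord, trait_cols, drop = FALSE])
  rownames(traits) <- species_order

  gd <- if (identical(guilds_path, traits_path)) tr else
    read.csv(guilds_path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!species_col %in% names(gd))
    stop("guilds file lacks species column '", species_col, "'")
  gids <- as.character(gd[[species_col]])
  if (anyDuplicated(gids))
    stop("duplicate species label '", gids[duplicated(gids)][1L],
         "' in guilds file")
  gmiss <- setdiff(species_order, gids)
  if (length(gmiss))
    stop("guilds file missing species: ", paste(gmiss, collapse = ", "))
  gord <- match(species_order, gids)
  guild <- if (guild_col %in% names(gd)) as.character(gd[[guild_col]][gord])
           else NULL
  if (is.null(detect_cols)) {
    detect <- NULL
  } else {
    bad <- setdiff(detect_cols, names(gd))
    if (length(bad))
      stop("guilds file lacks detection-covariate column(s): ",
           paste(bad, collapse = ", "))
    detect <- as.matrix(gd[gord, detect_cols, drop = FALSE])
    rownames(detect) <- species_order
  }
  species_meta(traits, guild = guild, detect_covariates = detect)
}

#' Write a data manifest describing files and transformations
#'
#' Records file paths, column mappings, and any transformations applied, as a
#' machine-readable JSON document.
#'
#' @param path output path (`.json`).
#' @param files named list of file paths.
#' @param layout the [survey_layout()] used.
#' @param transforms named list describing transformations (centering,
#'   log-scaling, ...).
#' @param seed integer seed associated with the run, if any.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, files = list(), layout = NULL,
                           transforms = list(), seed = NULL) {
  checksums <- lapply(files, function(f)
    if (file.exists(f)) unname(tools::md5sum(f)) else NA_character_)
  manifest <- list(
    package = "msnmix",
    version = as.character(utils::packageVersion("msnmix")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    files = files,
    checksums = checksums,
    layout = if (!is.null(layout)) unclass(layout),
    transforms = transforms)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}
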