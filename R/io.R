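#' Read a transect survey table
#'
#' Reads a CSV of bird detection events, one row per encounter: a flock of
#' \code{k} birds recorded together is one row with \code{count = k}.
#' Encounter-level rows are kept as-is (no aggregation) because the
#' flock-size index of the risk assessment needs the number of encounters
#' per species; aggregation happens later in
#' \code{\link{build_community_matrix}}.
#'
#' Required columns: \code{species_id}, \code{transect_id}, \code{habitat},
#' \code{season}, \code{count}, \code{height_band}, \code{zone}.
#' \code{habitat} must be one of urban/farmland/forest/wetland;
#' \code{season} one of spring/summer/autumn/winter; \code{height_band} one
#' of B0_5/B5_30/B30_50/B50_100/B100plus or empty (missing);
#' \code{zone} inside or outside.
#'
#' @param path path to a CSV file with a header row.
#' @return a \code{data.frame} of class \code{survey_table}, rows in file
#'   order.
#' @seealso \code{\link{build_community_matrix}}, \code{\link{assess_risk}}
#' @export
read_survey <- function(path) {
  if (!file.exists(path)) abort("survey file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) abort("no records in survey file: ", path)
  as_survey_table(df)
}

#' Validate a data frame of detection events
#'
#' @param df data frame with the columns documented in
#'   \code{\link{read_survey}}.
#' @return the validated \code{survey_table}.
#' @export
as_survey_table <- function(df) {
  req <- c("species_id", "transect_id", "habitat", "season", "count",
           "height_band", "zone")
  miss <- setdiff(req, names(df))
  if (length(miss)) abort("survey table missing column(s): ",
                          paste(miss, collapse = ", "))
  if (nrow(df) == 0L) abort("no records")
  df$species_id <- as.character(df$species_id)
  df$transect_id <- as.character(df$transect_id)
  df$habitat <- as.character(df$habitat)
  df$season <- as.character(df$season)
  df$zone <- as.character(df$zone)
  hb <- as.character(df$height_band)
  hb[is.na(hb) | hb == ""] <- NA_character_
  df$height_band <- hb

  check_vocab <- function(col, vocab, what) {
    bad <- which(!df[[col]] %in% vocab)
    if (length(bad)) abort("row ", bad[1], ": unknown ", what, " '",
                           df[[col]][bad[1]], "'")
  }
  if (any(!nzchar(df$species_id)))
    abort("row ", which(!nzchar(df$species_id))[1], ": empty species_id")
  check_vocab("habitat", HABITATS, "habitat")
  check_vocab("season", SEASONS, "season")
  check_vocab("zone", ZONES, "zone")
  badb <- which(!is.na(df$height_band) & !df$height_band %in% HEIGHT_BANDS)
  if (length(badb)) abort("row ", badb[1], ": unknown height_band '",
                          df$height_band[badb[1]], "'")
  if (!is.numeric(df$count) || any(is.na(df$count)) ||
      any(df$count != round(df$count)))
    abort("count must be a whole number for every record")
  badc <- which(df$count < 1)
  if (length(badc)) abort("row ", badc[1], ": count < 1")
  df$count <- as.integer(df$count)

  # a transect must sit in exactly one habitat
  th <- unique(df[, c("transect_id", "habitat")])
  dup <- th$transect_id[duplicated(th$transect_id)]
  if (length(dup)) abort("transect '", dup[1],
                         "' appears in more than one habitat")
  class(df) <- c("survey_table", "data.frame")
  df
}

#' Write a survey table back to CSV
#' @param survey a \code{survey_table}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_survey <- function(survey, path) {
  utils::write.csv(as.data.frame(survey), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a species trait table
#'
#' CSV with columns \code{species_id}, \code{body_mass} (grams, > 0),
#' \code{hwi} (hand-wing index, > 0), \code{diet} and \code{stratum}
#' (categorical labels). One row per species.
#'
#' @param path CSV path.
#' @return data frame of class \code{trait_table}.
#' @export
read_traits <- function(path) {
  if (!file.exists(path)) abort("trait file not found: ", path)
  as_trait_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_traits
#' @param df data frame with the trait columns.
#' @export
as_trait_table <- function(df) {
  req <- c("species_id", "body_mass", "hwi", "diet", "stratum")
  miss <- setdiff(req, names(df))
  if (length(miss)) abort("trait table missing column(s): ",
                          paste(miss, collapse = ", "))
  df$species_id <- as.character(df$species_id)
  dup <- df$species_id[duplicated(df$species_id)]
  if (length(dup)) abort("duplicate species_id in trait table: ", dup[1])
  for (col in c("body_mass", "hwi")) {
    v <- df[[col]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0))
      abort(col, " must be finite and > 0 for every species")
  }
  df$diet <- as.character(df$diet)
  df$stratum <- as.character(df$stratum)
  class(df) <- c("trait_table", "data.frame")
  df
}

#' Read a habitat-area table
#'
#' CSV with columns \code{habitat} and \code{area} (hectares, > 0). Returns
#' a named numeric vector; \code{sum()} of it is the total survey area.
#'
#' @param path CSV path.
#' @return named numeric vector of areas (class \code{habitat_areas}).
#' @export
read_habitat_areas <- function(path) {
  if (!file.exists(path)) abort("area file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("habitat", "area") %in% names(df)))
    abort("area table needs columns habitat, area")
  as_habitat_areas(stats::setNames(df$area, df$habitat))
}

#' @rdname read_habitat_areas
#' @param areas named numeric vector, habitat -> hectares.
#' @export
as_habitat_areas <- function(areas) {
  if (is.null(names(areas)) || any(!nzchar(names(areas))))
    abort("areas must be named by habitat")
  if (any(duplicated(names(areas)))) abort("duplicate habitat in area table")
  if (any(!is.finite(areas)) || any(areas <= 0))
    abort("all habitat areas must be finite and > 0")
  bad <- setdiff(names(areas), HABITATS)
  if (length(bad)) abort("unknown habitat in area table: ", bad[1])
  structure(as.numeric(areas), names = names(areas),
            class = "habitat_areas")
}

#' Read a rooted phylogeny in Newick format
#'
#' Thin wrapper over \code{ape::read.tree} that enforces the contract the
#' diversity metrics need: a single rooted tree, unique tip labels, branch
#' lengths present and non-negative. Polytomies and zero-length branches
#' are allowed.
#'
#' @param path Newick file path.
#' @return an \code{ape} \code{phylo} object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) abort("tree file not found: ", path)
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) abort("malformed Newick: ",
                                             conditionMessage(e)))
  if (is.null(tree)) abort("malformed Newick: ", path)
  if (inherits(tree, "multiPhylo"))
    abort("file contains more than one tree; a single rooted tree is required")
  validate_phylogeny(tree)
}

#' @rdname read_newick
#' @param tree a \code{phylo} object to validate.
#' @export
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) abort("not a phylo object")
  if (any(duplicated(tree$tip.label))) abort("duplicate tip labels in tree")
  if (is.null(tree$edge.length)) abort("tree has no branch lengths")
  if (any(tree$edge.length < 0)) abort("negative branch lengths in tree")
  if (!ape::is.rooted(tree)) abort("tree must be rooted")
  tree
}

#' Prune a phylogeny to a species set
#'
#' Keeps exactly the requested tips, collapsing internal nodes left with a
#' single descendant and summing the merged branch lengths, so patristic
#' distances among retained tips are unchanged.
#'
#' @param tree a \code{phylo}.
#' @param species character vector of tip labels to keep.
#' @return pruned \code{phylo}.
#' @export
prune_tree <- function(tree, species) {
  species <- unique(as.character(species))
  missing <- setdiff(species, tree$tip.label)
  if (length(missing))
    abort("species absent from tree: ", paste(missing, collapse = ", "))
  if (length(species) < 2)
    abort("cannot prune to fewer than 2 tips")
  ape::keep.tip(tree, species)
}

#' Build a species-by-assemblage community matrix
#'
#' Sums detection counts into an integer matrix with species as rows
#' (lexicographic order) and assemblages as columns. Assemblages are defined
#' by \code{group_by}: each transect (counts pooled over seasons), habitat,
#' season, habitat x season, or transect x season. Species absent from
#' every assemblage cannot occur (rows come from the records themselves),
#' so there are no all-zero rows.
#'
#' @param survey a \code{survey_table}.
#' @param group_by one of \code{"transect"}, \code{"habitat"},
#'   \code{"season"}, \code{"habitat_season"}, \code{"transect_season"}.
#' @return integer matrix with attribute \code{"meta"}: a data frame with
#'   one row per column giving the grouping keys (habitat and/or season and/or
#'   transect where defined).
#' @examples
#' df <- data.frame(species_id = c("A", "A", "B"), transect_id = "t1",
#'                  habitat = "forest", season = "spring",
#'                  count = c(5L, 3L, 2L), height_band = "B0_5",
#'                  zone = "outside")
#' m <- build_community_matrix(as_survey_table(df), "transect")
#' m["A", "t1"] # 8
#' @export
build_community_matrix <- function(survey,
    group_by = c("transect", "habitat", "season", "habitat_season",
                 "transect_season")) {
  group_by <- match.arg(group_by)
  if (nrow(survey) == 0L) abort("no records")
  key <- switch(group_by,
    transect = survey$transect_id,
    habitat = survey$habitat,
    season = survey$season,
    habitat_season = paste(survey$habitat, survey$season, sep = ":"),
    transect_season = paste(survey$transect_id, survey$season, sep = ":"))
  sp <- sort(unique(survey$species_id))
  gr <- sort(unique(key))
  m <- matrix(0L, length(sp), length(gr), dimnames = list(sp, gr))
  agg <- stats::aggregate(survey$count,
                          by = list(sp = survey$species_id, g = key), FUN = sum)
  m[cbind(match(agg$sp, sp), match(agg$g, gr))] <- as.integer(agg$x)

  t2h <- unique(data.frame(transect_id = survey$transect_id,
                           habitat = survey$habitat,
                           stringsAsFactors = FALSE))
  meta <- switch(group_by,
    transect = data.frame(assemblage = gr,
      habitat = t2h$habitat[match(gr, t2h$transect_id)],
      stringsAsFactors = FALSE),
    habitat = data.frame(assemblage = gr, habitat = gr,
      stringsAsFactors = FALSE),
    season = data.frame(assemblage = gr, season = gr,
      stringsAsFactors = FALSE),
    habitat_season = {
      parts <- strsplit(gr, ":", fixed = TRUE)
      data.frame(assemblage = gr,
                 habitat = vapply(parts, `[`, "", 1),
                 season = vapply(parts, `[`, "", 2),
                 stringsAsFactors = FALSE)
    },
    transect_season = {
      parts <- strsplit(gr, ":", fixed = TRUE)
      tid <- vapply(parts, `[`, "", 1)
      data.frame(assemblage = gr, transect_id = tid,
                 habitat = t2h$habitat[match(tid, t2h$transect_id)],
                 season = vapply(parts, `[`, "", 2),
                 stringsAsFactors = FALSE)
    })
  attr(m, "meta") <- meta
  attr(m, "group_by") <- group_by
  m
}
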