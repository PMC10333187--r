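# Vertex registry for the canonical circulation model.
#
# A vertex is a space through which blood flows.  The canonical table holds
# the 24 spaces of the normal heart and great vessels, numbered v1..v24 in
# the fixed order used throughout: edges, matrices and catalog scripts all
# refer to these 1-based indices.

.compartments <- c(
  "systemic_vein", "atrium", "ventricle", "great_artery", "pulmonary_artery",
  "lung", "pulmonary_vein", "aorta_segment", "aortic_branch", "target_organ",
  "shunt", "collateral", "other"
)

#' Canonical circulation vertex table
#'
#' Returns the ordered table of the 24 blood-containing spaces of the normal
#' heart and central vessels.  Vertex 24 (SCTO, systemic circulation target
#' organs) aggregates every systemic end-organ and closes the circulatory
#' circuit: systemic arteries drain into it and it returns blood to both
#' venae cavae.
#'
#' @return A data frame with columns `index` (1-based integer), `abbr`
#'   (unique abbreviation), `name` (full name) and `compartment`
#'   (anatomical class).
#' @examples
#' circulation_vertices()
#' @export
circulation_vertices <- function() {
  vertex_table(
    abbr = c("SVC", "IVC", "RA", "RV", "PT", "RPA", "LPA", "RL", "LL",
             "RUPV", "RLPV", "LUPV", "LLPV", "LA", "LV", "AAo", "AoA",
             "DAo", "IA", "LCCA", "LSCA", "RCCA", "RSCA", "SCTO"),
    name = c("superior vena cava", "inferior vena cava", "right atrium",
             "right ventricle", "pulmonary trunk", "right pulmonary artery",
             "left pulmonary artery", "right lung", "left lung",
             "right upper pulmonary vein", "right lower pulmonary vein",
             "left upper pulmonary vein", "left lower pulmonary vein",
             "left atrium", "left ventricle", "ascending aorta",
             "aortic arch", "descending aorta", "innominate artery",
             "left common carotid artery", "left subclavian artery",
             "right common carotid artery", "right subclavian artery",
             "systemic circulation target organs"),
    compartment = c("systemic_vein", "systemic_vein", "atrium", "ventricle",
                    "great_artery", "pulmonary_artery", "pulmonary_artery",
                    "lung", "lung",
                    "pulmonary_vein", "pulmonary_vein", "pulmonary_vein",
                    "pulmonary_vein", "atrium", "ventricle",
                    "aorta_segment", "aorta_segment", "aorta_segment",
                    "aortic_branch", "aortic_branch", "aortic_branch",
                    "aortic_branch", "aortic_branch", "target_organ")
  )
}

# Known extension vertices used by the catalog (each takes index n+1 when
# added to a graph) and recognised when reading matrices from CSV.
.extension_registry <- function() {
  data.frame(
    abbr = c("mBT", "PDA", "MAPCA", "PLSVC", "TrA"),
    name = c("modified Blalock-Taussig shunt", "patent ductus arteriosus",
             "major aortopulmonary collateral artery",
             "persistent left superior vena cava", "truncus arteriosus"),
    compartment = c("shunt", "shunt", "collateral", "systemic_vein",
                    "great_artery"),
    stringsAsFactors = FALSE
  )
}

#' Construct and validate a vertex table
#'
#' @param abbr Character vector of unique abbreviations.
#' @param name Character vector of full names (defaults to `abbr`).
#' @param compartment Character vector of compartment classes.
#' @param index Integer indices; must be `1..n` in order (default).
#' @return A validated vertex data frame.
#' @export
vertex_table <- function(abbr, name = abbr, compartment = "other",
                         index = seq_along(abbr)) {
  vt <- data.frame(index = as.integer(index), abbr = as.character(abbr),
                   name = as.character(name),
                   compartment = as.character(compartment),
                   stringsAsFactors = FALSE)
  validate_vertex_table(vt)
  vt
}

validate_vertex_table <- function(vt) {
  stopifnot(is.data.frame(vt),
            all(c("index", "abbr", "name", "compartment") %in% names(vt)))
  n <- nrow(vt)
  if (n < 1L) stop("vertex table must have at least one vertex")
  if (!identical(as.integer(vt$index), seq_len(n)))
    stop("vertex indices must form 1..n with no gaps")
  if (anyDuplicated(vt$abbr))
    stop("duplicated vertex abbreviation: ",
         paste(unique(vt$abbr[duplicated(vt$abbr)]), collapse = ", "))
  bad <- setdiff(vt$compartment, .compartments)
  if (length(bad))
    stop("unknown compartment class: ", paste(bad, collapse = ", "))
  invisible(vt)
}

# Resolve a vector of abbreviations or indices to integer indices within vt.
resolve_vertices <- function(x, vt) {
  if (is.character(x)) {
    idx <- match(x, vt$abbr)
    if (anyNA(idx))
      stop("unknown vertex abbreviation: ",
           paste(x[is.na(idx)], collapse = ", "))
    return(as.integer(idx))
  }
  x <- as.integer(x)
  if (any(is.na(x)) || any(x < 1L) || any(x > nrow(vt)))
    stop("vertex index out of range 1..", nrow(vt))
  x
}
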