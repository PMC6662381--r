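# The six microhabitat classification schemes. Species with more than one
# adult microhabitat carry a primary and a secondary record; each scheme
# collapses the pair (plus an external obligate/facultative arboreality
# status) to a single unordered state per species.

#' Microhabitat category codes
#'
#' Arboreal (A), cave (C), fossorial (F), saxicolous (S), terrestrial (T),
#' aquatic (W); SA (semiaquatic) exists only under the 7-state schemes.
#' @export
MICROHABITAT_STATES <- c("A", "C", "F", "S", "T", "W")

#' Recognized classification scheme identifiers
#'
#' Two designation rules (majority-rule "M": the primary category wins;
#' lenient "L": a species using terrestrial plus another microhabitat is
#' assigned the other one) crossed with three category sets: the six base
#' categories (6-M, 6-L), the same plus a semiaquatic state for species using
#' exactly terrestrial and aquatic microhabitats (7-M, 7-L), and the six base
#' categories with arboreality replaced by an external obligate (6-McM) or
#' obligate + facultative (6-McL) arboreal classification.
#' @export
CLASSIFICATION_SCHEMES <- c("6-M", "6-L", "7-M", "7-L", "6-McM", "6-McL")

.check_records <- function(records) {
  need <- c("species", "primary")
  if (!all(need %in% names(records))) {
    stop("records must have columns: ", paste(need, collapse = ", "))
  }
  records$species <- gsub("[[:space:]]+", "_", as.character(records$species))
  if (anyDuplicated(records$species)) {
    stop("duplicated species in microhabitat records")
  }
  if (!("secondary" %in% names(records))) records$secondary <- NA_character_
  if (!("mcentire_status" %in% names(records))) {
    records$mcentire_status <- "none"
  }
  records$primary <- as.character(records$primary)
  records$secondary <- as.character(records$secondary)
  records$secondary[records$secondary %in% c("", "NA")] <- NA_character_
  records$mcentire_status <- as.character(records$mcentire_status)
  records$mcentire_status[is.na(records$mcentire_status)] <- "none"
  bad <- !(records$primary %in% MICROHABITAT_STATES)
  if (any(bad)) {
    stop("invalid primary category for: ",
         paste(records$species[bad], collapse = ", "))
  }
  bad <- !is.na(records$secondary) &
    !(records$secondary %in% MICROHABITAT_STATES)
  if (any(bad)) {
    stop("invalid secondary category for: ",
         paste(records$species[bad], collapse = ", "))
  }
  same <- !is.na(records$secondary) & records$secondary == records$primary
  if (any(same)) {
    stop("secondary equals primary for: ",
         paste(records$species[same], collapse = ", "))
  }
  bad <- !(records$mcentire_status %in% c("obligate", "facultative", "none"))
  if (any(bad)) stop("mcentire_status must be obligate, facultative or none")
  records
}

#' Collapse primary/secondary microhabitat records to one state per species
#'
#' Applies one of the six classification schemes. Majority-rule schemes
#' return the primary category. Lenient schemes return the non-terrestrial
#' member of the pair when the primary is terrestrial and a secondary is
#' present. The 7-state schemes first map any species whose two categories
#' are exactly \{T, W\} (either order) to the semiaquatic state SA. The
#' McEntire variants then override arboreality for the species the external
#' classification covers: under 6-McM only obligate species are arboreal
#' (a facultative species the base scheme called arboreal falls back to its
#' secondary category, or T when it has none); under 6-McL both obligate
#' and facultative species are arboreal. Species without a McEntire status
#' keep their base-scheme state. Species with two non-terrestrial
#' categories keep their primary under lenient schemes, with a warning
#' naming them.
#'
#' @param records Data frame with columns `species`, `primary`, optional
#'   `secondary` (NA when absent) and `mcentire_status`
#'   (obligate/facultative/none).
#' @param scheme_id One of [CLASSIFICATION_SCHEMES].
#' @return A data frame (`species`, `state`) of class `scheme_assignment`
#'   with the scheme id in attribute `scheme`.
#' @export
apply_scheme <- function(records, scheme_id) {
  if (!(scheme_id %in% CLASSIFICATION_SCHEMES)) {
    stop("unknown scheme: ", scheme_id, "; recognized: ",
         paste(CLASSIFICATION_SCHEMES, collapse = ", "))
  }
  records <- .check_records(as.data.frame(records))
  lenient <- scheme_id %in% c("6-L", "7-L", "6-McL")
  seven <- scheme_id %in% c("7-M", "7-L")

  state <- records$primary
  if (lenient) {
    swap <- records$primary == "T" & !is.na(records$secondary)
    state[swap] <- records$secondary[swap]
    odd <- records$primary != "T" & !is.na(records$secondary) &
      records$secondary != "T"
    if (any(odd)) {
      warning("two non-terrestrial categories; primary kept for: ",
              paste(records$species[odd], collapse = ", "))
    }
  }
  if (seven) {
    semi <- !is.na(records$secondary) &
      ((records$primary == "T" & records$secondary == "W") |
       (records$primary == "W" & records$secondary == "T"))
    state[semi] <- "SA"
  }
  if (scheme_id %in% c("6-McM", "6-McL")) {
    arboreal_status <- if (scheme_id == "6-McM") "obligate" else
      c("obligate", "facultative")
    # the external classification only overrides species it actually
    # covers: classified-but-insufficient species lose arboreality,
    # unclassified species keep their base-scheme state
    demote <- state == "A" &
      records$mcentire_status %in%
        setdiff(c("obligate", "facultative"), arboreal_status)
    fallback <- ifelse(!is.na(records$secondary) & records$secondary != "A",
                       records$secondary, "T")
    state[demote] <- fallback[demote]
    state[records$mcentire_status %in% arboreal_status] <- "A"
  }

  out <- data.frame(species = records$species, state = state,
                    stringsAsFactors = FALSE)
  attr(out, "scheme") <- scheme_id
  class(out) <- c("scheme_assignment", class(out))
  out
}

# Normalize a states argument (scheme_assignment data frame or named
# character vector) to a named character vector.
.states_vector <- function(states) {
  if (is.data.frame(states)) {
    out <- as.character(states$state)
    names(out) <- as.character(states$species)
  } else {
    out <- as.character(states)
    names(out) <- names(states)
  }
  if (is.null(names(out)) || anyNA(names(out))) {
    stop("states must be named by species")
  }
  names(out) <- gsub("[[:space:]]+", "_", names(out))
  out
}
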