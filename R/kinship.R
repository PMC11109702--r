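# Kinship graph: typed parent->child edges from the register's parent links,
# spousal edges with validity intervals from the marriage table. Kin sets
# follow the field definitions used for household-composition and
# kin-proximity variables.

#' Build the kinship graph
#'
#' @param persons Data frame with `person_id`, `sex`, `birth_date`,
#'   `mother_id`, `father_id`.
#' @param marriages Data frame with `wife_id`, `husband_id`, `start_date`,
#'   `end_date` (NA while ongoing).
#' @param max_depth Blood-edge bound for the maternal/paternal kindred walk
#'   (edges counted from the linking parent).
#' @return List of class `kin_graph` with per-person precomputed id sets:
#'   `siblings`, `maternal`, `paternal`, `children`, plus `has_parent_ids`.
#' @export
build_kin_graph <- function(persons, marriages, max_depth = 3) {
  p <- persons
  n <- nrow(p)
  idx <- seq_len(n)
  names(idx) <- p$person_id
  mo <- unname(idx[p$mother_id]); fa <- unname(idx[p$father_id])
  if (any(!is.na(p$mother_id) & is.na(mo) & p$mother_id %in% p$person_id))
    data_error("unresolvable mother link")

  # cycle check: nobody is their own ancestor
  for (i in idx) {
    seen <- integer(0)
    frontier <- c(mo[i], fa[i])
    depth <- 0
    while (length(frontier <- frontier[!is.na(frontier)]) && depth < n + 1) {
      if (i %in% frontier) data_error("cyclic parentage")
      seen <- c(seen, frontier)
      frontier <- unique(c(mo[frontier], fa[frontier]))
      depth <- depth + 1
    }
  }
  if (any(p$sex[mo[!is.na(mo)]] != "female"))
    data_error("a mother edge does not originate from a female")
  if (any(p$sex[fa[!is.na(fa)]] != "male"))
    data_error("a father edge does not originate from a male")

  children <- vector("list", n)
  for (i in which(!is.na(mo))) children[[mo[i]]] <- c(children[[mo[i]]], i)
  for (i in which(!is.na(fa))) children[[fa[i]]] <- c(children[[fa[i]]], i)

  adj <- vector("list", n)   # undirected parent-child adjacency
  for (i in idx) adj[[i]] <- unique(c(mo[i], fa[i], children[[i]]))
  adj <- lapply(adj, function(v) v[!is.na(v)])

  sib <- lapply(idx, function(i) {
    s <- unique(c(if (!is.na(mo[i])) children[[mo[i]]],
                  if (!is.na(fa[i])) children[[fa[i]]]))
    setdiff(s, i)
  })

  side_set <- function(i, parent) {
    if (is.na(parent)) return(integer(0))
    # nodes within max_depth parent-child edges of the linking parent; the
    # walk never passes through the index or the index's siblings, whose
    # families are covered by the sister's/brother's-family sets (this also
    # keeps the other parent out of the side set)
    blocked <- c(i, sib[[i]])
    seen <- parent
    frontier <- parent
    for (d in seq_len(max_depth)) {
      frontier <- setdiff(unique(unlist(adj[frontier])), c(seen, blocked))
      if (!length(frontier)) break
      seen <- c(seen, frontier)
    }
    setdiff(seen, parent)
  }
  maternal <- lapply(idx, function(i) side_set(i, mo[i]))
  paternal <- lapply(idx, function(i) side_set(i, fa[i]))

  structure(list(
    person_id = p$person_id, sex = p$sex, birth_date = p$birth_date,
    mother = mo, father = fa, children = children, siblings = sib,
    maternal = maternal, paternal = paternal,
    has_parent_ids = !(is.na(p$mother_id) & is.na(p$father_id)),
    marriages = marriages, index = idx, max_depth = max_depth),
    class = "kin_graph")
}

# integer indices of spouses of person i under marriages active at `date`
spouses_at <- function(graph, i, date) {
  m <- graph$marriages
  if (!nrow(m)) return(integer(0))
  pid <- graph$person_id[i]
  act <- m$start_date <= date & (is.na(m$end_date) | m$end_date > date)
  hit <- act & (m$wife_id == pid | m$husband_id == pid)
  other <- ifelse(m$wife_id[hit] == pid, m$husband_id[hit], m$wife_id[hit])
  unname(graph$index[other])
}

#' Kin sets of a person at a date
#'
#' Five sets used by the family variables: `maternal` (blood kin reachable
#' through the mother, excluding the mother and the index's own siblings),
#' `paternal` (symmetric), `sisters_fam` (sisters aged 18 or over, their
#' spouses and children), `brothers_fam` (symmetric), and `nuclear` (parents
#' plus siblings under 18). Ages are evaluated at `at_date`.
#'
#' @param person_id Person identifier.
#' @param graph A `kin_graph`.
#' @param at_date Date at which ages and marriages are evaluated.
#' @return Named list of person-id character vectors.
#' @export
kin_sets <- function(person_id, graph, at_date) {
  i <- graph$index[[person_id]]
  at_date <- as.Date(at_date)
  age_of <- function(j) age_years(graph$birth_date[j], at_date)
  sibs <- graph$siblings[[i]]
  sib_fam <- function(sex) {
    eld <- sibs[graph$sex[sibs] == sex & age_of(sibs) >= 18]
    if (!length(eld)) return(integer(0))
    fam <- unlist(lapply(eld, function(s)
      c(s, spouses_at(graph, s, at_date), graph$children[[s]])))
    setdiff(unique(fam), i)
  }
  parents <- c(graph$mother[i], graph$father[i])
  parents <- parents[!is.na(parents)]
  nuc <- c(parents, sibs[age_of(sibs) < 18])
  ids <- function(v) graph$person_id[v]
  list(maternal = ids(graph$maternal[[i]]),
       paternal = ids(graph$paternal[[i]]),
       sisters_fam = ids(sib_fam("female")),
       brothers_fam = ids(sib_fam("male")),
       nuclear = ids(nuc))
}
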