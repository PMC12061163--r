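#' Hierarchical clinical code vocabulary
#'
#' A miniature analogue of a hierarchical clinical terminology (such as
#' SNOMED-CT), in which a parent code's meaning subsumes all of its
#' descendants. Each code carries exactly one role tag describing how it is
#' used by the caseness phenotype and the feature extractors.
#'
#' Roles:
#' \describe{
#'   \item{inclusion}{diagnoses on the caseness inclusion list (personality
#'     disorder, dysthymia, chronic depression, complex/chronic PTSD
#'     analogues).}
#'   \item{exclusion}{severe-mental-illness / dementia analogues whose
#'     presence removes a patient from the study population.}
#'   \item{psychiatric}{other mental-disorder codes (descendants of the
#'     mental-disorder root) that are not part of the caseness definition.}
#'   \item{antecedent}{adversity codes that generally precede the emergence
#'     of complex mental health difficulties (recorded before age 30).}
#'   \item{concurrent}{concerning findings or behaviours after age 30
#'     (self-harm, substance misuse, ...).}
#'   \item{referral}{referral types (psychological-therapy service
#'     analogues).}
#'   \item{other}{non-psychiatric codes.}
#' }
#'
#' @param codes data.frame with columns `code` (unique character ids),
#'   `role` (one of the roles above) and optionally `label`.
#' @param edges data.frame with columns `child`, `parent` giving the
#'   is-a links. The graph must be acyclic; a code may have several parents.
#' @return An object of class `code_vocabulary`: a list with elements
#'   `codes` (data.table) and `edges` (data.table).
#' @examples
#' vocab <- code_vocabulary(
#'   codes = data.frame(code = c("A", "B", "C"),
#'                      role = c("psychiatric", "psychiatric", "inclusion")),
#'   edges = data.frame(child = c("B", "C"), parent = c("A", "B"))
#' )
#' code_closure(vocab, "A")
#' @export
code_vocabulary <- function(codes, edges = NULL) {
  codes <- as.data.table(codes)
  if (!all(c("code", "role") %in% names(codes))) {
    stop("`codes` must have columns 'code' and 'role'", call. = FALSE)
  }
  if (!("label" %in% names(codes))) codes[, label := code]
  codes <- codes[, .(code = as.character(code), role = as.character(role),
                     label = as.character(label))]
  if (anyDuplicated(codes$code)) {
    stop("duplicate code identifiers in vocabulary", call. = FALSE)
  }
  valid_roles <- c("inclusion", "exclusion", "psychiatric", "antecedent",
                   "concurrent", "referral", "other")
  bad <- setdiff(unique(codes$role), valid_roles)
  if (length(bad)) {
    stop("unknown role tag(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (is.null(edges)) {
    edges <- data.table(child = character(), parent = character())
  } else {
    edges <- as.data.table(edges)[, .(child = as.character(child),
                                      parent = as.character(parent))]
  }
  unknown <- setdiff(unique(c(edges$child, edges$parent)), codes$code)
  if (length(unknown)) {
    stop("edges reference unknown code(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  vocab <- structure(list(codes = codes, edges = edges),
                     class = "code_vocabulary")
  if (.has_cycle(vocab)) stop("code hierarchy contains a cycle", call. = FALSE)
  vocab
}

# Kahn-style topological check for acyclicity
.has_cycle <- function(vocab) {
  edges <- vocab$edges
  if (!nrow(edges)) return(FALSE)
  nodes <- vocab$codes$code
  indeg <- table(factor(edges$child, levels = nodes))
  queue <- nodes[indeg == 0]
  removed <- 0L
  indeg <- as.integer(indeg)
  names(indeg) <- nodes
  children_of <- split(edges$child, edges$parent)
  while (length(queue)) {
    n <- queue[[1]]
    queue <- queue[-1]
    removed <- removed + 1L
    for (ch in children_of[[n]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  removed < length(nodes)
}

#' @export
print.code_vocabulary <- function(x, ...) {
  cat("<code_vocabulary> ", nrow(x$codes), " codes, ", nrow(x$edges),
      " is-a links\n", sep = "")
  print(x$codes[, .N, by = role])
  invisible(x)
}

#' Transitive descendant closure of a set of codes
#'
#' Returns the given root codes plus all of their transitive descendants in
#' the vocabulary hierarchy, mirroring the standard "parent code plus all
#' child codes" expansion used when searching clinical records with a
#' hierarchical terminology.
#'
#' @param vocab a [code_vocabulary()].
#' @param roots character vector of root codes; must all be in the
#'   vocabulary.
#' @return Character vector of codes (roots first, then descendants in
#'   breadth-first order, deduplicated).
#' @export
code_closure <- function(vocab, roots) {
  stopifnot(inherits(vocab, "code_vocabulary"))
  roots <- as.character(roots)
  unknown <- setdiff(roots, vocab$codes$code)
  if (length(unknown)) {
    stop("unknown root code(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  children_of <- split(vocab$edges$child, vocab$edges$parent)
  seen <- roots
  frontier <- roots
  while (length(frontier)) {
    nxt <- unique(unlist(children_of[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

#' Medications of interest
#'
#' The medication names, by class, used to define the recent-medication
#' caseness criterion: commonly-used antidepressants, antipsychotics, and
#' hypnotics/anxiolytics. Medication records are matched to these by
#' case-insensitive substring search on the product name.
#'
#' @return data.table with columns `name` and `class`
#'   (`antidepressant`, `antipsychotic`, `hypnotic_anxiolytic`).
#' @export
medications_of_interest <- function() {
  data.table(
    name = c("Clomipramine", "Citalopram", "Duloxetine", "Escitalopram",
             "Mirtazapine", "Paroxetine", "Sertraline", "Trazodone",
             "Venlafaxine", "Fluoxetine",
             "Risperidone", "Olanzapine", "Quetiapine", "Flupentixol",
             "Chlorpromazine", "Aripiprazole", "Haloperidol",
             "Diazepam", "Zopiclone"),
    class = c(rep("antidepressant", 10L),
              rep("antipsychotic", 7L),
              rep("hypnotic_anxiolytic", 2L))
  )
}

#' Default miniature code vocabulary
#'
#' A small, fully synthetic stand-in for a clinical terminology, with a
#' mental-disorder root subsuming the inclusion diagnoses, the
#' severe-mental-illness exclusion diagnoses and a set of generic psychiatric
#' codes (some with children), plus separate subtrees for childhood-adversity
#' (antecedent) codes, concerning-behaviour (concurrent) codes, referral
#' types, and non-psychiatric codes. It is deliberately tiny: the point is a
#' computable descendant closure and role structure, not terminological
#' realism.
#'
#' @return A [code_vocabulary()].
#' @export
default_vocabulary <- function() {
  codes <- rbind(
    data.table(code = "MD000", role = "psychiatric", label = "Mental disorder (root)"),
    # caseness inclusion list (children of the mental-disorder root)
    data.table(
      code = c("INC_PD", "INC_BPD", "INC_DYS", "INC_PDD", "INC_CHRDEP",
               "INC_CPTSD", "INC_CHRPTSD"),
      role = "inclusion",
      label = c("Personality disorder", "Borderline personality disorder",
                "Dysthymia", "Persistent depressive disorder",
                "Chronic depression",
                "Complex posttraumatic stress disorder",
                "Chronic post-traumatic stress disorder")),
    # exclusion: severe mental illness + dementia analogue
    data.table(
      code = c("EXC_BIP", "EXC_SCZ", "EXC_DEM"),
      role = "exclusion",
      label = c("Bipolar disorder", "Schizophrenia", "Dementia")),
    # generic psychiatric codes (not part of the caseness definition)
    data.table(
      code = c("PSY_ANX", "PSY_GAD", "PSY_PANIC", "PSY_DEP", "PSY_DEPEP",
               "PSY_RECDEP", "PSY_OCD", "PSY_PHOB", "PSY_EAT", "PSY_ANOR",
               "PSY_BUL", "PSY_ADHD", "PSY_ADJ", "PSY_SOMA", "PSY_INSOM",
               "PSY_GRIEF", "PSY_PTSDNOS", "PSY_MIXANXDEP", "PSY_IMPULSE",
               "PSY_DISSOC"),
      role = "psychiatric",
      label = c("Anxiety disorder", "Generalised anxiety disorder",
                "Panic disorder", "Depressive disorder",
                "Depressive episode", "Recurrent depressive disorder",
                "Obsessive-compulsive disorder", "Phobic disorder",
                "Eating disorder", "Anorexia nervosa", "Bulimia nervosa",
                "Attention deficit hyperactivity disorder",
                "Adjustment disorder", "Somatoform disorder",
                "Insomnia disorder", "Prolonged grief reaction",
                "Post-traumatic stress reaction NOS",
                "Mixed anxiety and depression", "Impulse control disorder",
                "Dissociative disorder")),
    # antecedent: childhood adversity subtree
    data.table(
      code = c("ANT000", "ANT_ABUSE", "ANT_NEGLECT", "ANT_ABANDON",
               "ANT_LAC", "ANT_PARSEP", "ANT_SCHEXC"),
      role = "antecedent",
      label = c("Childhood adversity (root)", "History of child abuse",
                "Childhood neglect", "Abandonment in childhood",
                "Looked-after child", "Parental separation",
                "Excluded from school")),
    # concurrent: concerning findings / behaviours subtree
    data.table(
      code = c("CON000", "CON_SELFHARM", "CON_OVERDOSE", "CON_SUBST",
               "CON_ALCOHOL", "CON_DRUG", "CON_VIOLENCE", "CON_HOUSING"),
      role = "concurrent",
      label = c("Concerning behaviour (root)", "Self-harm",
                "Drug overdose", "Substance misuse", "Alcohol misuse",
                "Drug misuse", "Victim of violence", "Housing instability")),
    # referral types
    data.table(
      code = c("REF_IAPT", "REF_CMHT", "REF_COUNS"),
      role = "referral",
      label = c("Referral to psychological therapy service",
                "Referral to community mental health team",
                "Referral to counselling")),
    # non-psychiatric
    data.table(
      code = c("OTH_DM", "OTH_ASTHMA", "OTH_HTN", "OTH_BACKPAIN"),
      role = "other",
      label = c("Diabetes mellitus", "Asthma", "Essential hypertension",
                "Low back pain"))
  )
  edges <- rbind(
    data.table(child = c("INC_PD", "INC_DYS", "INC_PDD", "INC_CHRDEP",
                         "INC_CPTSD", "INC_CHRPTSD",
                         "EXC_BIP", "EXC_SCZ",
                         "PSY_ANX", "PSY_DEP", "PSY_OCD", "PSY_PHOB",
                         "PSY_EAT", "PSY_ADHD", "PSY_ADJ", "PSY_SOMA",
                         "PSY_INSOM", "PSY_GRIEF", "PSY_PTSDNOS",
                         "PSY_MIXANXDEP", "PSY_IMPULSE", "PSY_DISSOC"),
               parent = "MD000"),
    data.table(child = c("INC_BPD"), parent = "INC_PD"),
    data.table(child = c("PSY_GAD", "PSY_PANIC"), parent = "PSY_ANX"),
    data.table(child = c("PSY_DEPEP", "PSY_RECDEP"), parent = "PSY_DEP"),
    data.table(child = c("PSY_ANOR", "PSY_BUL"), parent = "PSY_EAT"),
    data.table(child = c("ANT_ABUSE", "ANT_NEGLECT", "ANT_ABANDON",
                         "ANT_LAC", "ANT_PARSEP", "ANT_SCHEXC"),
               parent = "ANT000"),
    data.table(child = c("CON_SELFHARM", "CON_OVERDOSE", "CON_SUBST",
                         "CON_VIOLENCE", "CON_HOUSING"),
               parent = "CON000"),
    data.table(child = c("CON_ALCOHOL", "CON_DRUG"), parent = "CON_SUBST")
  )
  code_vocabulary(codes, edges)
}
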