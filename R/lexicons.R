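# Bundled miniature English lookup tables. The lemmatizer and POS tagger
# used on real data are pluggable; these defaults cover common inflections
# and function words seen in short symptom reports, with identity / "NN"
# fallbacks for anything unknown.

.lemma_table <- c(
  washing = "wash", washed = "wash", washes = "wash",
  hands = "hand", doors = "door", knobs = "knob", germs = "germ",
  checking = "check", checked = "check", checks = "check",
  locking = "lock", locked = "lock", locks = "lock",
  thoughts = "thought", worries = "worry", worried = "worry",
  worrying = "worry", fears = "fear", feared = "fear",
  knives = "knife", children = "child", kids = "kid",
  diseases = "disease", illnesses = "illness", harms = "harm",
  harmed = "harm", harming = "harm", hurting = "hurt", hurts = "hurt",
  touching = "touch", touched = "touch", touches = "touch",
  counting = "count", counted = "count", cleaning = "clean",
  cleaned = "clean", cleans = "clean", contaminated = "contaminate",
  contaminating = "contaminate", praying = "pray", prayed = "pray",
  relationships = "relationship", partners = "partner",
  accidents = "accident", cars = "car", houses = "house",
  fires = "fire", toilets = "toilet", showers = "shower",
  sicknesses = "sickness", arranging = "arrange", arranged = "arrange",
  ordering = "order", ordered = "order", repeating = "repeat",
  repeated = "repeat", avoiding = "avoid", avoided = "avoid",
  stoves = "stove", windows = "window", blades = "blade",
  needles = "needle", pills = "pill", numbers = "number",
  images = "image", urges = "urge", doubts = "doubt", doubting = "doubt"
)

.pos_table <- c(
  # adverbs
  quickly = "RB", really = "RB", very = "RB", constantly = "RB",
  always = "RB", never = "RB", again = "RB", too = "RB", not = "RB",
  faster = "RBR", fastest = "RBS",
  # modals
  can = "MD", could = "MD", might = "MD", must = "MD", will = "MD",
  would = "MD", should = "MD", may = "MD",
  # 3rd-person-singular-present verbs
  is = "VBZ", has = "VBZ", does = "VBZ", makes = "VBZ", gets = "VBZ",
  feels = "VBZ", goes = "VBZ",
  # gerunds
  washing = "VBG", checking = "VBG", cleaning = "VBG", going = "VBG",
  being = "VBG", thinking = "VBG", counting = "VBG", touching = "VBG",
  # past participles
  done = "VBN", been = "VBN", gone = "VBN", taken = "VBN", given = "VBN",
  # "to"
  to = "TO",
  # prepositions / subordinating conjunctions
  of = "IN", "in" = "IN", on = "IN", at = "IN", by = "IN", with = "IN",
  about = "IN", from = "IN", into = "IN", because = "IN", "if" = "IN",
  after = "IN", before = "IN", over = "IN", under = "IN",
  # personal pronouns
  i = "PRP", me = "PRP", you = "PRP", he = "PRP", she = "PRP", it = "PRP",
  we = "PRP", they = "PRP", them = "PRP", him = "PRP", her = "PRP",
  myself = "PRP", yourself = "PRP", himself = "PRP", herself = "PRP",
  itself = "PRP", ourselves = "PRP", themselves = "PRP",
  # common content words, kept by the default excluded-tag set
  germ = "NN", hand = "NN", door = "NN", knob = "NN", harm = "NN",
  thought = "NN", knife = "NN", child = "NN", disease = "NN",
  illness = "NN", contamination = "NN", relationship = "NN",
  partner = "NN", accident = "NN", fire = "NN", house = "NN", car = "NN",
  lock = "NN", toilet = "NN", shower = "NN", sick = "JJ", dirty = "JJ",
  sexual = "JJ", wash = "VB", check = "VB", hurt = "VB", hit = "VB"
)

#' Bundled lemma table, POS table and default excluded tags
#'
#' `default_lemma_table()` maps common English inflected forms to lemmas;
#' `default_pos_table()` maps common words to Penn Treebank tags;
#' `default_excluded_tags()` is the tag set removed from the analysis
#' vocabulary: adverbs (RB/RBR/RBS), modals (MD), third-person singular
#' present verbs (VBZ), gerunds (VBG), past participles (VBN), "to" (TO),
#' prepositions and subordinating conjunctions (IN), and personal pronouns
#' (PRP).
#'
#' @return A named character vector (tables) or character vector (tags).
#' @export
default_lemma_table <- function() .lemma_table

#' @rdname default_lemma_table
#' @export
default_pos_table <- function() .pos_table

#' @rdname default_lemma_table
#' @export
default_excluded_tags <- function() {
  c("RB", "RBR", "RBS", "MD", "VBZ", "VBG", "VBN", "TO", "IN", "PRP")
}

#' Lookup-table lemmatizer and POS tagger factories
#'
#' `lookup_lemmatizer(table)` returns a vectorised function mapping each
#' token to `table[token]` with identity fallback for unknown tokens (so the
#' lemmatizer is total and idempotent as long as the table maps onto lemmas
#' that are not themselves keys). `lookup_tagger(table, default)` returns a
#' vectorised word -> tag function with a fallback tag for unknown words.
#'
#' @param table Named character vector (`names` are the input forms).
#' @param default Tag assigned to words absent from the table.
#' @return A function taking a character vector and returning one of equal
#'   length.
#' @export
lookup_lemmatizer <- function(table = default_lemma_table()) {
  force(table)
  function(words) {
    out <- table[words]
    miss <- is.na(out)
    out[miss] <- words[miss]
    unname(out)
  }
}

#' @rdname lookup_lemmatizer
#' @export
lookup_tagger <- function(table = default_pos_table(), default = "NN") {
  force(table)
  force(default)
  function(words) {
    out <- table[words]
    out[is.na(out)] <- default
    unname(out)
  }
}
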