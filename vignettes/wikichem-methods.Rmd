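---
title: "wikichem: models, numerical choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{wikichem: models, numerical choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wikichem)
```

`wikichem` turns a corpus of wiki-markup chemistry pages into a searchable,
curated structure database. This vignette documents the chemistry model the
package commits to, the parameters that matter, what the synthetic-data
generator does and does not emulate, and the design decisions taken where
the problem was genuinely open.

## The SMILES dialect and valence model

The parser accepts the organic subset `B C N O P S F Cl Br I` (aromatic
`b c n o p s`), bracket atoms with isotope, charge, hydrogen count and
`@`/`@@` tetrahedral marks, ring-closure digits and `%nn`, bond symbols
`- = # : / \`, and dot-disconnected fragments. This covers everything a
chemical infobox corpus realistically exercises without implementing the
full Daylight grammar. Reaction SMILES and query atoms are out of scope.

Bare (non-bracket) atoms are assigned implicit hydrogens from fixed allowed
valence sets — B{3}, C{4}, N{3,5}, O{2}, P{3,5}, S{2,4,6}, halogens{1} —
choosing the smallest allowed valence not below the bond-order sum; a sum
above the maximum is a `VALENCE_ERROR`. Bracket atoms are exempt from
valence errors: an explicit specification wins, which matches common
toolkit behavior. Multi-fragment input is accepted; the largest component
is what gets indexed and searched, with a flag recording the fact.

Two boundary choices worth stating. A lone `H` (or `Hg`, `Na`, `Se`, ...)
outside brackets is classified `BARE_ATOM_NEEDS_BRACKETS` whenever the
characters form a recognizable element symbol, and `BAD_TOKEN` otherwise;
since `S`, `C`, `N`, `B`, `F`, `I` greedily match the organic subset,
symbols like `Sc` parse as sulfur + aromatic carbon (as SMILES requires)
and `Na` fails at the `a` — the grammar genuinely cannot distinguish these.
Atomic weights come from a table frozen in the package (abridged 2021
standard weights) so molecular weights are bit-reproducible; an isotope
mass number, when given, replaces the standard weight.

## Kekulization as perfect matching

An aromatic ring system is accepted iff single/double orders can be
assigned such that every aromatic atom that *requires* a double bond gets
exactly one. Lone-pair donors require none: `[nH]`/N with three
connections, `[n-]`, neutral aromatic O/S/Se, charged carbon, boron, and
any atom already carrying an exocyclic double bond. The assignment is a
perfect matching on the double-requiring subgraph, found by backtracking
that always extends the lowest-index unmatched atom with its lowest-index
candidate — which yields the matching whose sorted list of endpoint pairs
is lexicographically smallest, so kekulization is deterministic. The test
suite checks both validity and this tie-break against exhaustive
enumeration of all double-bond assignments.

Hückel electron counting is deliberately **not** enforced: kekulizability
is the acceptance test. The error browser this package feeds wants one
actionable cause per entry, so error precedence is syntax > kekulization >
valence, and only the single most specific issue is reported.

When kekulization fails, the repair search replaces bare aromatic `n`
tokens by `[nH]` — single tokens first (leftmost first), then larger
subsets in lexicographic order, capped at subsets of four — and returns the
first candidate that parses cleanly. This is exactly the dominant failure
mode in crowd-sourced corpora (unsubstituted pyrrole-type nitrogen written
`n`), and the returned fix is guaranteed to parse.

## Aromaticity perception

Rings written in alternating kekulé form are perceived as aromatic so that
`C1=CC=CC=C1` and `c1ccccc1` share one canonical form. Perception covers
5- and 6-membered rings of eligible elements where every atom either
carries an endocyclic double bond or is a lone-pair donor, and carries no
exocyclic double bond (keeping quinones and methylenecyclohexadienes
non-aromatic). Five-membered rings are included because fused
heteroaromatics demand it: a kekulé-encoded benzimidazole must
canonicalize identically to its aromatic form, which is impossible if only
six-membered rings are perceived. After perception the whole aromatic
system is re-kekulized with the deterministic matcher, so both surface
forms converge to one internal state. Perceived systems are still not
Hückel-counted — consistent with the kekulizability-is-acceptance policy.

## Canonicalization

Atom ranks come from Morgan-style iterative refinement. The initial
invariant is (element, charge, isotope, degree, total H, aromatic flag,
smallest-ring size); refinement folds in the sorted multiset of (bond
type, neighbor rank) pairs until the partition stabilizes. Remaining ties
are broken by doubling all ranks and promoting the lowest-index atom of
the lowest-ranked tied class, re-refining after each promotion. The writer
then emits each component depth-first from its rank-0 atom, neighbors in
ascending rank, ring-closure digits in order of first encounter (reused
after closing).

Stereo is part of structural identity: enantiomers get different canonical
strings, and a stereo-stripped variant is kept for near-duplicate
reporting. Tetrahedral parity is re-expressed via the permutation parity
between the parse-time neighbor order and the canonical output order
(parity flips iff the permutation is odd); double-bond cis/trans is stored
as a side relation between reference substituents and re-emitted as `/`
and `\` marks relative to the canonically chosen references.

Known limitations, stated plainly: (i) refinement-based canonicalization
can in principle leave non-equivalent atoms in one class on pathological
highly regular graphs, where the lowest-index tie-break would no longer be
label-independent — no such graphs arise from this package's molecule
space, and the invariance suite (500 molecules × 10 rewrites, byte
identity) guards the claim empirically; (ii) tautomers are *not*
normalized (so `c1cc[nH]c1` and kekulé 1H/2H-pyrrole drawings of different
tautomers stay distinct structures) — the cross-reference classifier
deliberately reduces tautomerism to the "same formula, different
structure" verdict; (iii) byte-compatibility with any external toolkit's
canonical form is a non-goal, only self-consistency is claimed, with an
independent toolkit used in the tests solely to certify that a curated
100-molecule set is pairwise distinct.

## The 512-bit fragment descriptor

The descriptor is a fragment dictionary fingerprint: bit *i* is set iff
dictionary fragment *i* occurs in the molecule at least `min_count[i]`
times as a substructure. The historical 512-fragment dictionary behind
this descriptor family is unpublished, so the package ships its own
versioned default (`wikichem-fragfp-v1`): element-count bits with
thresholds, linear paths of length 2–4 over C/N/O/S, multiple-bond motifs,
saturated and aromatic rings with common fusions and substitutions,
functional groups, padded with count-threshold variants to exactly 512
entries. Because every bit is a substructure predicate — and count
thresholds remain monotone under injective embeddings — *any* such
dictionary preserves the screening contract: substructure containment
implies bit-set containment. Screening effectiveness, by contrast, is a
quality property of the dictionary and is logged (not asserted) by the
acceptance suite; on the synthetic index the screen typically removes the
large majority of non-hits.

One subtlety is load-bearing: fragment SMILES like pyrrole must be written
`[nH]` to parse, but a bracket H count acts as a *minimum-H constraint* in
queries, and such constraints do not compose through embeddings onto bare
atoms (a fragment demanding H≥1 can sit in a query whose bare atom maps to
a target atom with no H). Descriptor evaluation therefore strips H
constraints from fragments, restoring monotonicity by construction.

Each descriptor is evaluated by running all 512 fragment substructure
searches; the only short-circuit is a provably sound element/size
pre-check. The 512 bits are serialized as 16 unsigned 32-bit words, word
`w` bit `j` holding global bit `32·w + j` (little-endian within the word);
R has no unsigned 32-bit type, so words travel as exact doubles and are
written to JSON as decimal integers.

## Matching and the two-step search

The subgraph-isomorphism core (C++, VF2-style backtracking with
rarest-element-first ordering) matches atoms on element, aromatic flag and
charge, and bonds exactly on order with aromatic-matches-aromatic. Bracket
query atoms impose their H count as a minimum; bare query atoms impose
none — the behavior a user expects from a drawn substructure query.
Kekulé/aromatic cross-matching is off by default (`aromatic_strict`),
keeping screening sound; a documented option relaxes it. An independent
pure-R injection-enumeration oracle validates the engine on hundreds of
random pairs.

Substructure search screens first (`(q & ~t) == 0` over the 16 words,
equivalently bit-subset), confirms second, and must equal brute-force
matching over the whole index — the acceptance suite asserts exactly that.
Ranking follows the interactive-search conventions: substructure hits by
ascending `|ΔMW|` (exact match first on ties, then page title for
byte-stable output); similarity by descending Tanimoto, ties by ascending
`|ΔMW|`, with any record equal to the query forced to rank 0; similarity
returns all records by default (`--top` truncates) since display cutoffs
belong to the caller.

## Scaffolds

The scaffold operator is the standard molecular framework: iteratively
prune terminal atoms, keeping what remains (rings plus linkers), then
re-attach atoms double- or triple-bonded to the framework (exocyclic
carbonyls stay; whole dangling acyl side chains go). Acyclic molecules
have no scaffold. Frequencies are counted per index record, so
stereo-distinct entries count separately — the frequency table counts
database entries, not abstract compounds. Scaffolds are reported as
canonical SMILES with counts; image layout is out of scope.

## The synthetic world

`synth_wiki_corpus()` emulates the statistical shape of a crowd-sourced
chemical infobox corpus, with defaults chosen once from the proportions
such corpora exhibit: about 14% of chemical pages carry no SMILES; parse
errors are dominated by the pyrrole-nitrogen mis-encoding (~2.7% of
entries) with a small tail (~0.4% each) of unclosed rings, unclosed
parentheses, bare metal symbols, unfixable kekulization failures, stray
tokens and valence errors; a small rate (~0.2%) of pages restate an
earlier page's molecule under a synonym title; a few percent of pages
carry stereo-divergent SMILES pairs or redundant identical-structure
pairs. Molecules are grown as random valence-respecting trees, optionally
around aromatic/aliphatic ring templates so kekulization paths get
coverage; emitted SMILES always parse. One integer seed drives a single
stream; corpora are byte-reproducible.

What the generator does *not* emulate — and hence what a green test does
not establish: realistic drug-like property distributions, heavy-element
and organometallic chemistry, very large ring systems, tautomer-rich
chemistry, or the actual error *texts* humans type (each error class is
represented by clean minimal exemplars). Conservation results
(kept + errors + dropped = parameters found) are exact by construction;
duplicate-group expectations are computed from the actually generated
structures, so rare random collisions are accounted for rather than
assumed away.

## Numerical and format choices

* Molecular weights are reported to 2 decimals; the weight table is frozen
  in-repo.
* Word packing (16 × uint32, little-endian within word) is frozen and
  versioned via the dictionary version string in the index header.
* Tanimoto of two all-zero fingerprints is defined as 1.0 (two molecules
  with no set bits are indistinguishable to the descriptor).
* All report orderings use byte-order (C-locale radix) string comparison,
  making outputs locale-independent; every tie ultimately breaks on page
  title or structure string, so outputs are byte-stable.
* The index header carries a build timestamp; pass `built_at` (CLI
  `--timestamp`) to pin it when byte-identical reruns matter.
* Pages containing tabs or newlines in titles are rejected at build time —
  the TSV and SMILES-list exports depend on it.
* When a page contains both a Chembox and a Drugbox, both are processed
  and each entry is tagged with its source template.
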