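#!/usr/bin/env python
"""Independent brute-force FRT-like site scanner.

Reads a FASTA file, scans every 34-nt window of each record with a
literal transcription of the identification rules, and prints
"record<TAB>offset0" for each accepted window. Used as a cross-check
oracle by the R test suite; shares no code with the R package.
"""
import sys

LEFT = ["G", "A", "A", "G", "T", "T", "C", "C", "T", "A", "T", "AT", "CT"]
RIGHT = ["AG", "AT", "A", "T", "A", "G", "G", "A", "A", "C", "T", "T", "C"]
ALLOWED = LEFT + RIGHT  # positions -13..-1 then 1..13
ACGT = set("ACGT")


def longest_true_run(bits):
    best = cur = 0
    for b in bits:
        cur = cur + 1 if b else 0
        best = max(best, cur)
    return best


def accepted(w):
    if set(w) - ACGT:
        return False
    sp = w[13:21]
    if sp[0] != "T" or sp[7] != "A":
        return False
    if sum(c in "GC" for c in sp) > 4:
        return False
    run = 1
    for a, b in zip(w, w[1:]):
        run = run + 1 if a == b else 1
        if run > 4:
            return False
    m = []
    for k in range(26):
        col = k if k < 13 else k + 8
        m.append(w[col] in ALLOWED[k])
    p8 = m[9:17]
    if sum(p8) < 5:
        return False
    for seg in (p8[0:4], p8[4:8]):
        for a, b in zip(seg, seg[1:]):
            if not a and not b:
                return False
    if not p8[3] and not p8[4]:
        return False
    if w[12] == "G" or w[21] == "C":
        return False
    if not (m[6] or m[19]):
        return False
    if sum(m[0:13]) < 5 and sum(m[13:26]) < 5:
        return False
    if max(longest_true_run(m[0:13]), longest_true_run(m[13:26])) < 6:
        return False
    return True


def read_fasta(path):
    name, chunks = None, []
    with open(path) as fh:
        for line in fh:
            line = line.strip()
            if line.startswith(">"):
                if name is not None:
                    yield name, "".join(chunks)
                name, chunks = line[1:].split()[0], []
            else:
                chunks.append(line.upper())
    if name is not None:
        yield name, "".join(chunks)


def main():
    for path in sys.argv[1:]:
        for name, seq in read_fasta(path):
            for i in range(len(seq) - 33):
                if accepted(seq[i:i + 34]):
                    sys.stdout.write("%s\t%d\n" % (name, i))


if __name__ == "__main__":
    main()
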