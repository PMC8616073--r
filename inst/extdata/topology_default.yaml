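# Default nine-clone topology of the immune-tumor ecosystem.
#
# This is the package's own construction of the reference mutation tree and
# antigen-pattern matrix (a synthetic stand-in for the model's published
# pattern, built to satisfy its stated constraints): component 1 is borne by
# exactly the four first-generation clones T11..T14; second/third-generation
# clones each bear one private neo-antigen component; the host bears three
# components of its own (2, 8, 9), so the host-directed effector populations
# behave identically.
#
# Labels T<i><k>: generation i, branch k.
n_components: 9
populations:
  - name: T11
    components: [1]
  - name: T12
    parent: T11
    components: [1]
  - name: T13
    parent: T11
    components: [1]
  - name: T14
    parent: T11
    components: [1]
  - name: T21
    parent: T11
    components: [3]
  - name: T22
    parent: T12
    components: [4]
  - name: T23
    parent: T13
    components: [5]
  - name: T24
    parent: T14
    components: [6]
  - name: T31
    parent: T21
    components: [7]
  - name: H
    host: true
    components: [2, 8, 9]
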