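command: split
config_hash: adda1462
seed: 1
package: genospace 0.1.0
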