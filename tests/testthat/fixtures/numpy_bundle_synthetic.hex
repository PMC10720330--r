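504b03042d000000000000002100ce4184dbffffffffffffffff05001400522e6e707901001000e000000000000000e000000000000000934e554d50
59010076007b276465736372273a20273c6638272c2027666f727472616e5f6f72646572273a2046616c73652c20277368617065273a2028322c2032
2c2033292c207d2020202020202020202020202020202020202020202020202020202020202020202020202020202020202020202020202020202020
20200a9ca223b9fcc7f6bfbea1f0d93a38f43fa6d6fb8d76dcebbfb665c0594a96d0bff486fbc8ad49b3bf4c1aa37554b5e7bfe529abe97ae2f5bf77
4eb340bbc3e43f02637d03931bd73f5d18e945ed3effbf486de2e47ec7024087c5a86bedfdee3f504b03042d000000000000002100b1182585ffffff
ffffffffff050014007a2e6e70790100100090000000000000009000000000000000934e554d5059010076007b276465736372273a20273c6938272c
2027666f727472616e5f6f72646572273a2046616c73652c20277368617065273a2028322c292c207d20202020202020202020202020202020202020
20202020202020202020202020202020202020202020202020202020202020202020202020202020200a06000000000000000800000000000000504b
03042d000000000000002100ac3b7f89ffffffffffffffff05001400452e6e70790100100090000000000000009000000000000000934e554d505901
0076007b276465736372273a20273c6638272c2027666f727472616e5f6f72646572273a2046616c73652c20277368617065273a2028322c292c207d
202020202020202020202020202020202020202020202020202020202020202020202020202020202020202020202020202020202020202020202020
0a0000000000000ac00000000000001240504b03042d000000000000002100436439dfffffffffffffffff05001400462e6e707901001000e0000000
00000000e000000000000000934e554d5059010076007b276465736372273a20273c6638272c2027666f727472616e5f6f72646572273a2046616c73
652c20277368617065273a2028322c20322c2033292c207d202020202020202020202020202020202020202020202020202020202020202020202020
202020202020202020202020202020202020200ade3d40f7e54ce8bf0e881057cedeec3fbd38f1d58ee2ddbf6d73637ac212afbf97aab4c5353ee93f
2ae09ee74f1bf4bf9e7aa4c16d6de23f0da7cccd3762f63f300f99f22128f53fb935e9b6442ed3bf1afcfd62b6e4ec3f3bfe0b0401f2f9bf504b0102
2d032d000000000000002100ce4184dbe0000000e0000000050000000000000000000000800100000000522e6e7079504b01022d032d000000000000
002100b118258590000000900000000500000000000000000000008001170100007a2e6e7079504b01022d032d000000000000002100ac3b7f899000
0000900000000500000000000000000000008001de010000452e6e7079504b01022d032d000000000000002100436439dfe0000000e0000000050000
0000000000000000008001a5020000462e6e7079504b05060000000004000400cc000000bc0300000000
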