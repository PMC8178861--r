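word	role	synonyms
boy	subject	son|brother
girl	subject	daughter|sister
mother	subject	woman|lady|mom
cookie	object	biscuit
jar	object
stool	object	chair
sink	object	basin
water	object
window	object
curtain	object
plate	object	dish
kitchen	place
floor	place
cupboard	place	cabinet
counter	place
fall	action
reach	action
take	action	steal
wash	action	clean
dry	action
overflow	action	spill
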